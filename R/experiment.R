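#' Named experiment configurations for the figure-style set-ups
#'
#' Returns a run configuration (a plain named list, YAML
#' round-trippable) for each of the standard experiments of the study:
#' spiral genesis in the cellular automaton, target/spiral formation in
#' the FHN lattice (static and developmental-path variability),
#' pacemaker-driven pattern ensembles of the hybrid CA/ODE model, and
#' the developmental-path cAMP relay ensembles.  Defaults are
#' reduced-scale (60 x 60 lattices, small ensembles); set
#' \code{reduced = FALSE} for the full 100 x 100 set-ups.
#'
#' @param name experiment name; one of \code{"fig_ca_spiral"},
#'   \code{"fig_fhn_target"}, \code{"fig_fhn_spiral"},
#'   \code{"fig_fhn_lowexc"}, \code{"fig_fhn_static_gauss"},
#'   \code{"fig_fhn_path"}, \code{"fig_levine_early"},
#'   \code{"fig_levine_ensemble"},
#'   \code{"fig_levine_ensemble_clustered"},
#'   \code{"fig_goldbeter_waves"}, \code{"fig_goldbeter_voronoi"}
#' @param reduced use reduced-scale defaults
#' @param seed base seed
#' @return named list (the run configuration)
#' @export
figureConfig <- function(name, reduced = TRUE, seed = 1) {
    n <- if (reduced) 60L else 100L
    cfg <- switch(name,
        fig_ca_spiral = list(model = "ca", nx = 100L, ny = 100L, r = 1L,
                             frontLength = 50L, nSteps = 600L),
        fig_fhn_target = list(model = "fhn_static", nx = n, ny = n,
                              cBase = 0.025, cPacemaker = 0, T = 400,
                              init = "rest"),
        fig_fhn_spiral = list(model = "fhn_static", nx = n, ny = n,
                              cBase = 0.021, T = 400, init = "spiral"),
        fig_fhn_lowexc = list(model = "fhn_static", nx = n, ny = n,
                              cBase = 0.024, cLow = 0.030,
                              lowFraction = 0.400, cPacemaker = 0,
                              T = 600, init = "rest"),
        fig_fhn_static_gauss = list(model = "fhn_static", nx = n, ny = n,
                                    cBase = 0.024, gaussianSd = 0.006,
                                    T = 600, init = "rest"),
        fig_fhn_path = list(model = "fhn_path", nx = n, ny = n,
                            Delta = 500, T = 2000, init = "rest"),
        fig_levine_early = list(model = "levine", nx = n, ny = n,
                                layout = "random", fraction = 0.195,
                                beta = 0.2, pF = 0.002, E0 = 0, T = 150),
        fig_levine_ensemble = list(model = "levine", nx = n, ny = n,
                                   layout = "random", fraction = 0.190,
                                   beta = 0.2, pF = 0.002, E0 = 0,
                                   T = 150, runs = if (reduced) 100L else 1000L),
        fig_levine_ensemble_clustered = list(model = "levine", nx = n,
                                             ny = n, layout = "clustered",
                                             fraction = 0.190, beta = 0.2,
                                             pF = 0.002, E0 = 0, T = 150,
                                             runs = if (reduced) 100L else 1000L),
        fig_goldbeter_waves = list(model = "goldbeter", nx = n, ny = n,
                                   Delta = 25, T = 220,
                                   runs = if (reduced) 50L else 100L),
        fig_goldbeter_voronoi = list(model = "goldbeter", nx = n, ny = n,
                                     Delta = 15, T = 220, layout = "fixed5",
                                     bonusOffset = 30,
                                     runs = if (reduced) 50L else 250L),
        stop(sprintf("unknown experiment name '%s'", name)))
    cfg$name <- name
    cfg$seed <- as.integer(seed)
    cfg
}

.knownConfigKeys <- c("name", "model", "seed", "nx", "ny", "r",
                      "frontLength", "nSteps", "cBase", "cLow",
                      "lowFraction", "cPacemaker", "gaussianSd", "T",
                      "init", "Delta", "layout", "fraction", "beta", "pF",
                      "E0", "runs", "bonusOffset", "recordEvery")

.simulateFromConfig <- function(cfg, runSeed) {
    switch(cfg$model,
        ca = {
            g <- caOpenWavefrontInit(cfg$nx, cfg$ny, cfg$frontLength,
                                     r = cfg$r)
            caSimulate(g, nSteps = cfg$nSteps, recordEvery = 2L)
        },
        fhn_static = {
            cmap <- fhnExcitabilityMap(cfg$nx, cfg$ny, cBase = cfg$cBase,
                cLow = cfg$cLow,
                lowFraction = if (is.null(cfg$lowFraction)) 0 else cfg$lowFraction,
                cPacemaker = cfg$cPacemaker,
                gaussianSd = if (is.null(cfg$gaussianSd)) 0 else cfg$gaussianSd,
                seed = runSeed)
            fhnSimulate(cmap = cmap, T = cfg$T, seed = runSeed,
                        init = cfg$init, recordEvery = 100L)
        },
        fhn_path = {
            off <- sampleTimeOffsets(cfg$nx, cfg$ny, cfg$Delta,
                                     seed = runSeed)
            fhnSimulate(offsets = off, T = cfg$T, seed = runSeed,
                        init = cfg$init, recordEvery = 200L)
        },
        levine = {
            pm <- pacemakerLayout(cfg$nx, cfg$ny, kind = cfg$layout,
                                  fraction = cfg$fraction, seed = runSeed)
            p <- levineParams(beta = cfg$beta, pF = cfg$pF)
            levineSimulate(pm, p, T = cfg$T, seed = runSeed + 1L,
                           E0 = cfg$E0)
        },
        goldbeter = {
            off <- sampleTimeOffsets(cfg$nx, cfg$ny, cfg$Delta,
                                     seed = runSeed)
            fixed <- NULL
            bonus <- 0
            if (identical(cfg$layout, "fixed5")) {
                pm <- pacemakerLayout(cfg$nx, cfg$ny, kind = "fixed5",
                                      extraFraction = 0, seed = runSeed)
                fixed <- which(propertyValues(pm) == 1, arr.ind = TRUE)
                bonus <- cfg$bonusOffset
            }
            goldbeterSimulate(off, pp = gbPathParams(Delta = cfg$Delta),
                              T = cfg$T, fixedSites = fixed,
                              bonusOffset = bonus)
        },
        stop(sprintf("unknown model '%s'", cfg$model)))
}

#' Run a configured experiment end to end
#'
#' Executes simulate, detect and (for ensembles) the occupancy
#' statistics for a run configuration, writing the movie of the first
#' run, per-run event CSVs and a log file with the effective
#' configuration.  Ensemble member \code{k} uses seed
#' \code{seed + k - 1}.
#'
#' @param config a configuration list (see \code{\link{figureConfig}})
#' @param outDir output directory (created if missing)
#' @param writeMovie write the first run's movie as TIFF
#' @return list with \code{plots} (per-run \linkS4class{EventPlot}s),
#'   \code{occupancy} (tips \linkS4class{OccupancyMap} for ensembles,
#'   else NULL) and \code{paths} (written artifact paths)
#' @export
runExperiment <- function(config, outDir = tempfile("experiment"),
                          writeMovie = FALSE) {
    unknown <- setdiff(names(config), .knownConfigKeys)
    if (length(unknown) > 0)
        stop(sprintf("unknown config keys: %s",
                     paste(unknown, collapse = ", ")))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    runs <- if (is.null(config$runs)) 1L else as.integer(config$runs)
    paths <- character(0)
    plots <- vector("list", runs)
    for (k in seq_len(runs)) {
        cube <- .simulateFromConfig(config, runSeed = config$seed + k - 1L)
        if (k == 1L && writeMovie) {
            mp <- file.path(outDir, sprintf("%s_movie.tif", config$name))
            writeCube(cube, mp)
            paths <- c(paths, mp)
        }
        ep <- buildEventPlot(cube)
        fp <- file.path(outDir, sprintf("%s_events_run%03d.csv",
                                        config$name, k))
        writeEvents(ep, fp)
        paths <- c(paths, fp)
        plots[[k]] <- ep
    }
    occ <- NULL
    if (runs > 1) {
        occ <- occupancyMap(plots, kind = "spiral_tip")
        op <- file.path(outDir, sprintf("%s_tip_occupancy.csv", config$name))
        utils::write.csv(counts(occ), op, row.names = FALSE)
        paths <- c(paths, op)
    }
    logPath <- file.path(outDir, sprintf("%s_log.yml", config$name))
    writeConfig(c(config, list(package = "PatternEvents",
                               rversion = as.character(getRversion()))),
                logPath)
    paths <- c(paths, logPath)
    list(plots = plots, occupancy = occ, paths = paths)
}
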