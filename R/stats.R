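#' Accumulate an occupancy map over an ensemble of event plots
#'
#' Per-site counts of events of one kind over all runs (sub-pixel
#' events binned to the nearest site).
#'
#' @param plots list of \linkS4class{EventPlot}s sharing one lattice
#'   shape
#' @param kind event kind to count
#' @return an \linkS4class{OccupancyMap}
#' @export
occupancyMap <- function(plots, kind = c("spiral_tip", "target_origin")) {
    kind <- match.arg(kind)
    stopifnot(length(plots) >= 1)
    sh <- latticeShape(plots[[1]])
    for (p in plots)
        if (!identical(latticeShape(p), sh))
            stop("all event plots must share the lattice shape")
    m <- matrix(0, sh[1], sh[2])
    for (p in plots) m <- m + topDownView(p, kind)
    new("OccupancyMap", counts = m, nRuns = length(plots), kind = kind)
}

#' Gaussian smoothing of a lattice map
#'
#' Isotropic Gaussian convolution with standard deviation \code{radius}
#' (separable kernel truncated at four standard deviations), with
#' reflecting boundaries; the total sum is preserved.  \code{radius = 0}
#' returns the input unchanged.
#'
#' @param m numeric matrix
#' @param radius Gaussian standard deviation in sites (>= 0)
#' @return smoothed matrix of the same shape
#' @export
gaussianSmooth <- function(m, radius) {
    if (radius < 0) stop("radius must be non-negative")
    if (radius == 0) return(m)
    hw <- max(1L, ceiling(4 * radius))
    k <- stats::dnorm(-hw:hw, sd = radius)
    k <- k / sum(k)
    # half-sample symmetric reflection: fold any integer index into 1..n
    reflectIdx <- function(i, n) {
        j <- (i - 1) %% (2 * n)
        ifelse(j < n, j + 1, 2 * n - j)
    }
    conv1 <- function(x) {
        n <- length(x)
        xp <- x[reflectIdx(seq(1 - hw, n + hw), n)]
        stats::convolve(xp, k, type = "filter")
    }
    sm <- apply(m, 2, conv1)
    t(apply(sm, 1, conv1))
}

#' Spearman rank correlation between two lattice maps
#'
#' @param a,b numeric matrices of the same shape, each with at least two
#'   distinct values
#' @return Spearman correlation over all sites (average ranks for ties)
#' @export
spearmanMap <- function(a, b) {
    stopifnot(identical(dim(a), dim(b)))
    if (length(unique(as.vector(a))) < 2 ||
        length(unique(as.vector(b))) < 2)
        stop("undefined correlation: constant map")
    stats::cor(as.vector(a), as.vector(b), method = "spearman")
}

#' Correlation between event maps and a property map versus filter
#' radius
#'
#' For every run and every Gaussian filter radius: build the per-run
#' event maps, smooth both members of each requested pair, and compute
#' the Spearman correlation; report the mean and the standard error of
#' the mean (sd/sqrt(n)) across runs.  Runs in which a map is constant
#' (e.g. no events) contribute no correlation for that pair and are
#' dropped from its average.
#'
#' @param runPlots list of \linkS4class{EventPlot}s (>= 2 runs)
#' @param propertyMap a \linkS4class{CellPropertyMap}, or a list of one
#'   such map per run (for ensembles in which the property itself is
#'   redrawn every run, e.g. developmental-path time offsets)
#' @param pairs subset of \code{c("origins_vs_property",
#'   "tips_vs_origins", "tips_vs_property")}
#' @param radii Gaussian filter radii (sites)
#' @return data.frame with columns pair, radius, mean_rho, sem_rho,
#'   n_used
#' @export
correlationVsRadius <- function(runPlots, propertyMap,
                                pairs = c("origins_vs_property",
                                          "tips_vs_origins",
                                          "tips_vs_property"),
                                radii = c(1, 2, 4, 8, 16)) {
    stopifnot(length(runPlots) >= 2)
    pairs <- match.arg(pairs, several.ok = TRUE)
    propList <- if (is.list(propertyMap) && !is(propertyMap, "CellPropertyMap"))
        lapply(propertyMap, propertyValues)
    else rep(list(propertyValues(propertyMap)), length(runPlots))
    stopifnot(length(propList) == length(runPlots))
    tipMaps <- lapply(runPlots, topDownView, kind = "spiral_tip")
    orgMaps <- lapply(runPlots, topDownView, kind = "target_origin")
    res <- list()
    for (rad in radii) {
        propS <- lapply(propList, gaussianSmooth, radius = rad)
        tipS <- lapply(tipMaps, gaussianSmooth, radius = rad)
        orgS <- lapply(orgMaps, gaussianSmooth, radius = rad)
        for (pr in pairs) {
            rhos <- vapply(seq_along(runPlots), function(i) {
                a <- switch(pr,
                            origins_vs_property = orgS[[i]],
                            tips_vs_origins = tipS[[i]],
                            tips_vs_property = tipS[[i]])
                b <- switch(pr,
                            origins_vs_property = propS[[i]],
                            tips_vs_origins = orgS[[i]],
                            tips_vs_property = propS[[i]])
                if (length(unique(as.vector(a))) < 2 ||
                    length(unique(as.vector(b))) < 2) return(NA_real_)
                spearmanMap(a, b)
            }, numeric(1))
            ok <- !is.na(rhos)
            n <- sum(ok)
            res[[length(res) + 1L]] <- data.frame(
                pair = pr, radius = rad,
                mean_rho = if (n > 0) mean(rhos[ok]) else NA_real_,
                sem_rho = if (n > 1) stats::sd(rhos[ok]) / sqrt(n) else 0,
                n_used = n, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, res)
}

#' Sample points on the (clipped) Voronoi edge set of a seed set
#'
#' Brute-force construction: every pairwise perpendicular bisector is
#' sampled at \code{step}-site resolution and a sample is kept when its
#' two generating seeds are jointly nearest among all seeds (within
#' tolerance), i.e. when it lies on a true Voronoi edge inside the
#' lattice rectangle.
#'
#' @param seeds two-column matrix of seed coordinates (x, y)
#' @param shape lattice shape c(nx, ny)
#' @param step sampling resolution in sites
#' @return two-column matrix of edge sample points
#' @export
voronoiEdgePoints <- function(seeds, shape, step = 0.25) {
    seeds <- as.matrix(seeds)
    n <- nrow(seeds)
    if (n < 3) stop("need at least 3 seeds")
    if (qr(scale(seeds, scale = FALSE))$rank < 2)
        stop("need at least 3 non-collinear seeds")
    diag2 <- sqrt(shape[1]^2 + shape[2]^2)
    pts <- list()
    for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
            mid <- (seeds[a, ] + seeds[b, ]) / 2
            d <- seeds[b, ] - seeds[a, ]
            len <- sqrt(sum(d^2))
            if (len < 1e-9) next
            tang <- c(-d[2], d[1]) / len
            s <- seq(-diag2, diag2, by = step)
            px <- mid[1] + s * tang[1]
            py <- mid[2] + s * tang[2]
            inside <- px >= 0 & px <= shape[1] - 1 &
                      py >= 0 & py <= shape[2] - 1
            if (!any(inside)) next
            px <- px[inside]; py <- py[inside]
            dab <- sqrt((px - seeds[a, 1])^2 + (py - seeds[a, 2])^2)
            dmin <- rep(Inf, length(px))
            for (kk in seq_len(n)) {
                if (kk == a || kk == b) next
                dk <- sqrt((px - seeds[kk, 1])^2 + (py - seeds[kk, 2])^2)
                dmin <- pmin(dmin, dk)
            }
            keep <- dab <= dmin + 1e-9
            if (any(keep)) pts[[length(pts) + 1L]] <- cbind(px[keep], py[keep])
        }
    }
    if (length(pts) == 0) stop("no Voronoi edges inside the lattice")
    do.call(rbind, pts)
}

#' Voronoi-edge proximity statistic with a permutation null
#'
#' Mean Euclidean distance of event points (e.g. spiral tips) to the
#' Voronoi edge set of a seed set (e.g. effective pacemakers), compared
#' with \code{nPerm} uniform re-placements of the same number of points
#' on the lattice.  The one-sided p-value is the fraction of
#' permutations with a mean distance smaller than or equal to the
#' observed one (with the add-one convention, so the minimum attainable
#' p is \code{1/(nPerm + 1)}).
#'
#' @param tips two-column matrix (or data.frame with x, y) of event
#'   coordinates
#' @param seeds two-column matrix of seed coordinates (>= 3,
#'   non-collinear)
#' @param shape lattice shape c(nx, ny)
#' @param nPerm number of permutations
#' @param seed optional integer seed for the null draws
#' @param step edge sampling resolution
#' @return list with \code{mean_distance}, \code{null_mean},
#'   \code{p_value}, \code{n_tips}
#' @export
voronoiEdgeStat <- function(tips, seeds, shape, nPerm = 999, seed = NULL,
                            step = 0.25) {
    if (is.data.frame(tips)) tips <- cbind(tips$x, tips$y)
    tips <- as.matrix(tips)
    if (nrow(tips) < 1) stop("need at least one tip")
    edges <- voronoiEdgePoints(seeds, shape, step)
    meanDist <- function(pt) {
        mean(vapply(seq_len(nrow(pt)), function(i) {
            sqrt(min((edges[, 1] - pt[i, 1])^2 + (edges[, 2] - pt[i, 2])^2))
        }, numeric(1)))
    }
    obs <- meanDist(tips)
    if (!is.null(seed)) set.seed(seed)
    nullD <- vapply(seq_len(nPerm), function(k) {
        meanDist(cbind(stats::runif(nrow(tips), 0, shape[1] - 1),
                       stats::runif(nrow(tips), 0, shape[2] - 1)))
    }, numeric(1))
    list(mean_distance = obs, null_mean = mean(nullD),
         p_value = (1 + sum(nullD <= obs)) / (nPerm + 1),
         n_tips = nrow(tips))
}
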