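#' Synthetic movie specification
#'
#' Kinematic wave movies with exact, analytic event ground truth,
#' emulating the statistical structure of rescaled dark-field
#' Dictyostelium wave movies: rotating Archimedean spirals and expanding
#' target (ring) waves on a lattice with additive Gaussian noise.  There
#' are no dynamics; intensities are prescribed, so every ground-truth
#' event location is known exactly.
#'
#' @param kind \code{"archimedean_spiral"}, \code{"target"} or
#'   \code{"mixed"}
#' @param centers two-column matrix of source centres (0-based x, y)
#' @param periods rotation/emission period per source (frames)
#' @param waveSpeeds radial wave speed per source (sites/frame)
#' @param chiralities per-spiral chirality, \code{+1} (left) or
#'   \code{-1} (right); ignored for targets
#' @param t0 start frame per target source (0-based; ignored for
#'   spirals)
#' @param noiseSd additive Gaussian noise standard deviation (signal
#'   amplitude is 1)
#' @param nFrames number of frames
#' @param shape lattice shape c(nx, ny)
#' @param seed integer seed for the noise
#' @return a list of class \code{"SyntheticSpec"}
#' @export
syntheticSpec <- function(kind = c("archimedean_spiral", "target", "mixed"),
                          centers, periods = 20, waveSpeeds = 0.5,
                          chiralities = 1, t0 = 30, noiseSd = 0,
                          nFrames = 120, shape = c(100, 100), seed = 1) {
    kind <- match.arg(kind)
    centers <- matrix(as.numeric(centers), ncol = 2)
    ns <- nrow(centers)
    if (ns >= 2) {
        dmin <- min(stats::dist(centers))
        if (dmin < 5) stop("source centres closer than 5 sites")
    }
    rec <- function(x) rep_len(x, ns)
    stopifnot(all(periods > 0), all(waveSpeeds > 0), noiseSd >= 0)
    structure(list(kind = kind, centers = centers, periods = rec(periods),
                   waveSpeeds = rec(waveSpeeds),
                   chiralities = rec(chiralities), t0 = rec(t0),
                   noiseSd = noiseSd, nFrames = as.integer(nFrames),
                   shape = as.integer(shape), seed = as.integer(seed)),
              class = "SyntheticSpec")
}

# hard domain partition of competing wave systems: each site carries
# only the wave that reaches it first (colliding wave systems annihilate
# at the equal-arrival-time shock, where the phases of synchronized
# sources agree exactly, so the composite is continuous there)
.partitionSources <- function(parts, arrival) {
    if (length(parts) == 1) return(parts[[1]])
    best <- arrival[[1]]
    out <- parts[[1]]
    for (s in 2:length(parts)) {
        sel <- arrival[[s]] < best
        out[sel] <- parts[[s]][sel]
        best <- pmin(best, arrival[[s]])
    }
    out
}

#' Generate a rotating-spiral movie with ground truth
#'
#' Per source the intensity is the non-negative dark-field-like signal
#' \code{(1 + cos(kr * r - chi * theta - omega * t))/2} (an Archimedean
#' spiral rotating with period \code{period}); each site carries the
#' wave of its nearest source only (colliding wave systems annihilate,
#' they do not interfere) and additive Gaussian noise is applied.  The ground-truth
#' event plot lists the spiral tip at each centre in every frame with
#' the specified chirality.
#'
#' @param spec a \code{\link{syntheticSpec}} of kind
#'   \code{"archimedean_spiral"}
#' @return list with \code{cube} (\linkS4class{SpaceTimeCube}) and
#'   \code{truth} (\linkS4class{EventPlot})
#' @export
makeSpiralMovie <- function(spec) {
    sh <- spec$shape
    X <- matrix(seq_len(sh[1]) - 1, sh[1], sh[2])
    Y <- matrix(seq_len(sh[2]) - 1, sh[1], sh[2], byrow = TRUE)
    set.seed(spec$seed)
    arr <- array(0, dim = c(sh[1], sh[2], spec$nFrames))
    ns <- nrow(spec$centers)
    rs <- lapply(seq_len(ns), function(s)
        sqrt((X - spec$centers[s, 1])^2 + (Y - spec$centers[s, 2])^2))
    for (t in seq_len(spec$nFrames)) {
        parts <- lapply(seq_len(ns), function(s) {
            th <- atan2(Y - spec$centers[s, 2], X - spec$centers[s, 1])
            kr <- 2 * pi / (spec$waveSpeeds[s] * spec$periods[s])
            om <- 2 * pi / spec$periods[s]
            0.5 * (1 + cos(kr * rs[[s]] - spec$chiralities[s] * th - om * (t - 1)))
        })
        arr[, , t] <- .partitionSources(parts, rs)
    }
    if (spec$noiseSd > 0)
        arr <- arr + array(stats::rnorm(length(arr), 0, spec$noiseSd),
                           dim = dim(arr))
    truth <- do.call(rbind, lapply(seq_len(nrow(spec$centers)), function(s) {
        data.frame(kind = "spiral_tip",
                   chirality = if (spec$chiralities[s] > 0) "left" else "right",
                   x = spec$centers[s, 1], y = spec$centers[s, 2],
                   t = seq_len(spec$nFrames) - 1, stringsAsFactors = FALSE)
    }))
    list(cube = SpaceTimeCube(arr, modelName = "synthetic_spiral",
                              seed = spec$seed),
         truth = EventPlot(truth, shape = sh, nFrames = spec$nFrames))
}

#' Generate an expanding target-wave movie with ground truth
#'
#' Per source the intensity is \code{(1 + cos(kr * r - omega * (t - t0)))/2}
#' gated (smoothly) to start at frame \code{t0} and to extend only to
#' the radius the front has reached (an expanding ring system).  The ground truth
#' lists one target origin per source at its centre and start frame.
#'
#' @param spec a \code{\link{syntheticSpec}} of kind \code{"target"}
#' @return list with \code{cube} and \code{truth} as in
#'   \code{\link{makeSpiralMovie}}
#' @export
makeTargetMovie <- function(spec) {
    sh <- spec$shape
    X <- matrix(seq_len(sh[1]) - 1, sh[1], sh[2])
    Y <- matrix(seq_len(sh[2]) - 1, sh[1], sh[2], byrow = TRUE)
    set.seed(spec$seed)
    arr <- array(0, dim = c(sh[1], sh[2], spec$nFrames))
    nsrc <- nrow(spec$centers)
    rs <- lapply(seq_len(nsrc), function(s)
        sqrt((X - spec$centers[s, 1])^2 + (Y - spec$centers[s, 2])^2))
    # first-arrival partition: site x belongs to the source whose front
    # reaches it first
    arrival <- lapply(seq_len(nsrc), function(s)
        spec$t0[s] + rs[[s]] / spec$waveSpeeds[s])
    for (t in seq_len(spec$nFrames)) {
        parts <- lapply(seq_len(nsrc), function(s) {
            tt <- (t - 1) - spec$t0[s]
            if (tt < 0) return(matrix(0, sh[1], sh[2]))
            kr <- 2 * pi / (spec$waveSpeeds[s] * spec$periods[s])
            om <- 2 * pi / spec$periods[s]
            # smooth expanding-front gate (sigmoid ramp ~1.5 sites wide)
            gate <- 1 / (1 + exp((rs[[s]] - spec$waveSpeeds[s] * tt) / 1.5))
            gate * 0.5 * (1 + cos(kr * rs[[s]] - om * tt))
        })
        arr[, , t] <- .partitionSources(parts, arrival)
    }
    if (spec$noiseSd > 0)
        arr <- arr + array(stats::rnorm(length(arr), 0, spec$noiseSd),
                           dim = dim(arr))
    truth <- if (nsrc > 0)
        data.frame(kind = "target_origin", chirality = "none",
                   x = spec$centers[, 1], y = spec$centers[, 2],
                   t = spec$t0[seq_len(nsrc)], stringsAsFactors = FALSE)
    else emptyEvents()
    list(cube = SpaceTimeCube(arr, modelName = "synthetic_target",
                              seed = spec$seed),
         truth = EventPlot(truth, shape = sh, nFrames = spec$nFrames))
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching of detected events to ground-truth events
#' of the same kind within a spatial matching radius and a temporal
#' window; reports precision, recall, localisation error and chirality
#' accuracy.  For tip ground truth (one event per frame and centre) the
#' matching is done per persistent source: a source counts as recalled
#' if any detection matches it.
#'
#' @param detected an \linkS4class{EventPlot} (detector output)
#' @param truth an \linkS4class{EventPlot} (ground truth)
#' @param kind event kind to evaluate
#' @param radius spatial matching radius (sites)
#' @param window temporal matching window (frames; ignored for tips,
#'   which persist)
#' @return list with precision, recall, mean localisation error,
#'   chirality accuracy (tips only)
#' @export
matchEvents <- function(detected, truth,
                        kind = c("spiral_tip", "target_origin"),
                        radius = 3, window = 20) {
    kind <- match.arg(kind)
    det <- events(detected); det <- det[det$kind == kind, , drop = FALSE]
    tru <- events(truth); tru <- tru[tru$kind == kind, , drop = FALSE]
    if (kind == "spiral_tip") {
        # collapse the per-frame truth to unique sources
        src <- unique(tru[, c("x", "y", "chirality")])
        if (nrow(det) == 0)
            return(list(precision = if (nrow(src) == 0) 1 else 0,
                        recall = if (nrow(src) == 0) 1 else 0,
                        locError = NA_real_, chiralityAcc = NA_real_))
        dSrc <- function(i) sqrt((src$x - det$x[i])^2 + (src$y - det$y[i])^2)
        near <- vapply(seq_len(nrow(det)), function(i) {
            d <- dSrc(i); j <- which.min(d)
            if (d[j] <= radius) j else NA_integer_
        }, integer(1))
        matched <- !is.na(near)
        locErr <- vapply(which(matched), function(i) {
            j <- near[i]
            sqrt((src$x[j] - det$x[i])^2 + (src$y[j] - det$y[i])^2)
        }, numeric(1))
        chirOK <- det$chirality[matched] == src$chirality[near[matched]]
        list(precision = mean(matched),
             recall = mean(seq_len(nrow(src)) %in% near[matched]),
             locError = if (any(matched)) mean(locErr) else NA_real_,
             chiralityAcc = if (any(matched)) mean(chirOK) else NA_real_)
    } else {
        if (nrow(tru) == 0)
            return(list(precision = if (nrow(det) == 0) 1 else 0,
                        recall = 1, locError = NA_real_,
                        chiralityAcc = NA_real_))
        if (nrow(det) == 0)
            return(list(precision = 0, recall = 0, locError = NA_real_,
                        chiralityAcc = NA_real_))
        usedT <- logical(nrow(tru))
        match_j <- rep(NA_integer_, nrow(det))
        for (i in order(det$t)) {
            d <- sqrt((tru$x - det$x[i])^2 + (tru$y - det$y[i])^2)
            ok <- d <= radius & abs(tru$t - det$t[i]) <= window & !usedT
            if (any(ok)) {
                j <- which(ok)[which.min(d[ok])]
                usedT[j] <- TRUE
                match_j[i] <- j
            }
        }
        matched <- !is.na(match_j)
        locErr <- vapply(which(matched), function(i) {
            j <- match_j[i]
            sqrt((tru$x[j] - det$x[i])^2 + (tru$y[j] - det$y[i])^2)
        }, numeric(1))
        list(precision = mean(matched), recall = mean(usedT),
             locError = if (any(matched)) mean(locErr) else NA_real_,
             chiralityAcc = NA_real_)
    }
}
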