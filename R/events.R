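.wrapAngle <- function(x) atan2(sin(x), cos(x))

#' Dominant oscillation period of a movie
#'
#' Median over clearly oscillating sites of each site's spectral peak
#' period (discrete Fourier transform of the demeaned series,
#' frequencies above the movie-length fundamental).  Sites are sampled
#' on a regular grid, so the estimate is deterministic.
#'
#' @param cube a \linkS4class{SpaceTimeCube}
#' @param nSample number of sites sampled
#' @return period in frames (falls back to \code{nt/5} for
#'   non-oscillating movies)
#' @export
estimateDominantPeriod <- function(cube, nSample = 100) {
    arr <- frames(cube)
    d <- dim(arr)
    nt <- d[3]
    fallback <- max(4, floor(nt / 5))
    flat <- matrix(arr, d[1] * d[2], nt)
    sds <- sqrt(rowMeans((flat - rowMeans(flat))^2))
    # restrict to clearly oscillating sites: noise-only background
    # otherwise distorts the estimate
    active <- which(sds >= 0.5 * stats::median(sds[sds > 1e-12]))
    if (length(active) == 0) return(fallback)
    step <- max(1L, floor(length(active) / nSample))
    sites <- active[seq(1L, length(active), by = step)]
    kmax <- floor(nt / 2)
    if (kmax < 2) return(fallback)
    periods <- vapply(sites, function(s) {
        x <- flat[s, ] - mean(flat[s, ])
        p <- Mod(stats::fft(x))[2:(kmax + 1)]^2   # harmonics 1..kmax
        nt / which.max(p)
    }, numeric(1))
    # the movie-length fundamental signals a non-oscillating trend
    med <- stats::median(periods)
    if (med >= nt * 0.9) return(fallback)
    max(4L, as.integer(round(med)))
}

#' Delay-coordinate phase embedding of a movie
#'
#' Per-site phase angle from the plane spanned by the referenced signal
#' and its delayed copy,
#' \code{phase(t) = atan2(x(t - delay) - ref, x(t) - ref)},
#' which advances by \code{2*pi} per oscillation period.  By default the
#' reference level is the site's \emph{trailing-window mean}, which
#' centres the oscillation even when a site only starts oscillating
#' partway through the movie, and stays close to the baseline for
#' strongly duty-cycled (spike-train-like) signals; a fixed scalar
#' \code{refLevel} can be supplied instead.  Because the
#' amplitude scale cancels inside \code{atan2}, the phase is invariant
#' under affine intensity rescaling of the movie.
#'
#' Sites are masked (\code{NA}) frame-wise wherever the trailing-window
#' peak-to-peak range falls below \code{maskRel} times the movie's
#' oscillation amplitude scale (the 98th percentile of the per-site
#' full signal ranges): a phase is only defined where the signal
#' actually oscillates.  Constant sites are therefore always fully
#' masked, and no phase is emitted before one full window of history
#' exists.
#'
#' @param cube a \linkS4class{SpaceTimeCube} (>= 3 frames)
#' @param refLevel optional fixed reference level (default: windowed
#'   midrange per site and frame)
#' @param delay embedding delay in frames (default: quarter of the
#'   dominant period)
#' @param window trailing window for midrange and amplitude masking
#'   (frames; default: two dominant periods, so the reference level is
#'   insensitive to cycle-to-cycle spike-interval variation)
#' @param maskRel amplitude mask level as a fraction of the movie's
#'   5th-95th percentile intensity range
#' @return 3-d array of phases in \code{(-pi, pi]} with \code{NA} at
#'   masked site-frames; \code{attr(, "frameOffset")} gives the number
#'   of initial frames consumed by the delay
#' @export
phaseEmbed <- function(cube, refLevel = NULL, delay = NULL, window = NULL,
                       maskRel = 0.3) {
    arr <- frames(cube)
    d <- dim(arr)
    n <- d[1] * d[2]
    if (d[3] < 3) stop("phase embedding needs at least 3 frames")
    if (is.null(delay) || is.null(window)) {
        period <- estimateDominantPeriod(cube)
        if (is.null(delay)) delay <- max(1L, round(period / 4))
        if (is.null(window)) window <- max(delay + 2L, 2L * as.integer(period))
    }
    delay <- as.integer(delay)
    window <- as.integer(window)
    if (delay >= d[3]) stop("delay must be smaller than the frame count")
    flat <- matrix(arr, n, d[3])
    nt <- d[3] - delay
    # pass 1: trailing-window extremes per site and frame
    tEval <- seq_len(d[3])
    tEval <- tEval[tEval > delay & tEval >= window]
    rngM <- matrix(NA_real_, n, d[3])
    midM <- matrix(NA_real_, n, d[3])
    csum <- t(apply(flat, 1, cumsum))
    for (t in tEval) {
        sl <- lapply((t - window + 1L):t, function(q) flat[, q])
        hi <- do.call(pmax, sl)
        lo <- do.call(pmin, sl)
        rngM[, t] <- hi - lo
        prev <- if (t - window >= 1L) csum[, t - window] else 0
        midM[, t] <- (csum[, t] - prev) / window
    }
    # amplitude floor relative to the oscillation amplitude scale of
    # the movie: the top of the trailing-range distribution itself
    finiteR <- rngM[, tEval, drop = FALSE]
    floorAmp <- max(maskRel * stats::quantile(finiteR, 0.95, names = FALSE),
                    1e-12)
    ph <- matrix(NA_real_, n, nt)
    for (t in tEval) {
        mid <- if (is.null(refLevel)) midM[, t] else refLevel
        p <- atan2(flat[, t - delay] - mid, flat[, t] - mid)
        p[rngM[, t] < floorAmp] <- NA_real_
        ph[, t - delay] <- p
    }
    out <- array(ph, dim = c(d[1], d[2], nt))
    attr(out, "frameOffset") <- delay
    out
}

#' Detect spiral tips (phase singularities) in one phase frame
#'
#' Sums the wrapped phase differences around every 2x2 plaquette; a
#' winding of (approximately) \code{+-2*pi} marks a phase singularity at
#' the plaquette centre.  Positive winding (counter-clockwise in array
#' coordinates) is labelled \code{"left"}, negative \code{"right"}.
#'
#' @param phaseFrame numeric matrix of phases (NA = masked)
#' @param tFrame frame index (0-based) attached to the returned events
#' @return data.frame of spiral-tip events (kind, chirality, x, y, t)
#' @export
detectSpiralTips <- function(phaseFrame, tFrame = 0) {
    nx <- nrow(phaseFrame); ny <- ncol(phaseFrame)
    p00 <- phaseFrame[-nx, -ny]
    p10 <- phaseFrame[-1, -ny]
    p11 <- phaseFrame[-1, -1]
    p01 <- phaseFrame[-nx, -1]
    wind <- .wrapAngle(p10 - p00) + .wrapAngle(p11 - p10) +
            .wrapAngle(p01 - p11) + .wrapAngle(p00 - p01)
    hit <- which(!is.na(wind) & abs(wind) > pi, arr.ind = TRUE)
    if (nrow(hit) == 0) return(emptyEvents())
    data.frame(kind = "spiral_tip",
               chirality = ifelse(wind[hit] > 0, "left", "right"),
               x = hit[, 1] - 0.5, y = hit[, 2] - 0.5,
               t = tFrame, stringsAsFactors = FALSE)
}

# greedy frame-to-frame linking of tip detections into tracks; a track
# may bridge up to maxGap missing frames (cores can be masked for a
# frame or two); returns the input rows belonging to tracks that are
# present in >= minFrames frames
.persistentTips <- function(tips, radius = 2, minFrames = 3, maxGap = 2) {
    if (nrow(tips) == 0) return(tips)
    tips <- tips[order(tips$t, tips$x, tips$y), , drop = FALSE]
    track <- integer(nrow(tips))
    nTracks <- 0L
    ts <- sort(unique(tips$t))
    recentIdx <- integer(0)
    for (tt in ts) {
        cur <- which(tips$t == tt)
        recentIdx <- recentIdx[tips$t[recentIdx] >= tt - maxGap - 1]
        # most recent detection of each live track
        prev <- recentIdx[!duplicated(track[recentIdx], fromLast = TRUE)]
        used <- logical(length(prev))
        for (i in cur) {
            linked <- FALSE
            if (length(prev) > 0) {
                dd <- sqrt((tips$x[prev] - tips$x[i])^2 +
                           (tips$y[prev] - tips$y[i])^2)
                dd[used] <- Inf
                jb <- which.min(dd)
                if (length(jb) == 1 && is.finite(dd[jb]) && dd[jb] <= radius) {
                    track[i] <- track[prev[jb]]
                    used[jb] <- TRUE
                    linked <- TRUE
                }
            }
            if (!linked) {
                nTracks <- nTracks + 1L
                track[i] <- nTracks
            }
        }
        recentIdx <- c(recentIdx, cur)
    }
    span <- tapply(tips$t, track, function(v) length(unique(v)))
    keep <- track %in% as.integer(names(span)[span >= minFrames])
    tips <- tips[keep, , drop = FALSE]
    track <- track[keep]
    # a rotor has a single handedness: assign each track its majority
    # chirality (individual-frame winding signs can flip under noise)
    if (nrow(tips) > 0) {
        for (tr in unique(track)) {
            sel <- track == tr
            tab <- table(tips$chirality[sel])
            tips$chirality[sel] <- names(tab)[which.max(tab)]
        }
    }
    tips
}

#' Detect target-wave origins in a movie
#'
#' A target origin is a site that crosses the activation threshold
#' upward at a time when no site within \code{radiusR} crossed during
#' the preceding \code{windowW} frames, and around which the activated
#' area grows over the following \code{windowW} frames (an expanding
#' front).  Duplicate origins within \code{radiusR} and \code{windowW}
#' are merged to the earliest.  When the movie opens with activity
#' already present (waves established before recording), the first
#' \code{windowW} frames carry no usable history and are skipped; a
#' movie that opens quiet is scanned from the start.
#'
#' @param cube a \linkS4class{SpaceTimeCube}
#' @param actThreshold activation threshold (default: midpoint of the
#'   movie's 5th and 95th intensity percentiles)
#' @param radiusR exclusion/merge radius in sites
#' @param windowW history/growth window in frames (default: one
#'   dominant period)
#' @return data.frame of target-origin events (kind, chirality, x, y, t)
#' @export
detectTargetOrigins <- function(cube, actThreshold = NULL, radiusR = 10,
                                windowW = NULL) {
    arr <- frames(cube)
    d <- dim(arr); nt <- d[3]
    if (is.null(actThreshold)) {
        qs <- stats::quantile(arr, c(0.05, 0.95), names = FALSE)
        actThreshold <- mean(qs)
    }
    if (is.null(windowW)) windowW <- estimateDominantPeriod(cube)
    windowW <- max(2L, as.integer(round(windowW)))
    above <- arr >= actThreshold
    # disc offsets for the growth neighbourhood
    rr <- as.integer(ceiling(radiusR))
    disc <- expand.grid(di = -rr:rr, dj = -rr:rr)
    disc <- disc[disc$di^2 + disc$dj^2 <= radiusR^2, ]
    brush <- EBImage::makeBrush(2L * rr + 1L, "disc")
    lastCross <- matrix(-Inf, d[1], d[2])
    accepted <- data.frame(x = numeric(0), y = numeric(0), t = numeric(0))
    # waves already present at the first frame leave the early history
    # unusable; a quiet opening frame means the history is genuinely empty
    warmup <- if (mean(above[, , 1]) > 0.01) windowW else 0L
    for (t in 2:nt) {
        cross <- above[, , t] & !above[, , t - 1]
        if (t > warmup && any(cross)) {
            # sites whose radius-R neighbourhood saw a crossing within
            # the preceding window (one dilation per frame)
            recent <- lastCross >= (t - windowW)
            blocked <- if (any(recent))
                EBImage::imageData(EBImage::dilate(EBImage::Image(recent * 1),
                                                   brush)) > 0.5
            else recent
            idx <- which(cross & !blocked, arr.ind = TRUE)
            for (r in seq_len(nrow(idx))) {
                i <- idx[r, 1]; j <- idx[r, 2]
                ii <- pmin(pmax(i + disc$di, 1L), d[1])
                jj <- pmin(pmax(j + disc$dj, 1L), d[2])
                nb <- cbind(ii, jj)
                # expanding-front check on the local activated area,
                # over half a period (afterwards the leading ring can
                # already be leaving the neighbourhood again)
                kMax <- min(max(2L, windowW %/% 2L), nt - t)
                if (kMax < 2) next
                areas <- vapply(0:kMax, function(k)
                    sum(above[, , t + k][nb]), numeric(1))
                if (areas[kMax + 1] <= areas[1]) next
                if (stats::cor(seq_along(areas), areas) < 0.5) next
                # merge: suppressed if near an accepted origin
                if (nrow(accepted) > 0) {
                    dd <- sqrt((accepted$x - (i - 1))^2 +
                               (accepted$y - (j - 1))^2)
                    if (any(dd <= radiusR & (t - 1 - accepted$t) <= windowW))
                        next
                }
                accepted <- rbind(accepted,
                                  data.frame(x = i - 1, y = j - 1, t = t - 1))
            }
        }
        lastCross[cross] <- t
    }
    if (nrow(accepted) == 0) return(emptyEvents())
    data.frame(kind = "target_origin", chirality = "none",
               x = accepted$x, y = accepted$y, t = accepted$t,
               stringsAsFactors = FALSE)
}

#' Build the pattern-event plot of a movie
#'
#' Runs the phase embedding, per-frame spiral-tip detection with
#' temporal persistence filtering (a tip must persist for at least
#' \code{persistence} frames within a 2-site radius), and target-origin
#' detection, then merges everything into a sorted
#' \linkS4class{EventPlot}.
#'
#' The frame-wise amplitude mask of \code{\link{phaseEmbed}} restricts
#' tip detection to site-frames whose signal actually oscillates, so
#' phase defects on a (near-)quiescent background -- before wave onset
#' or after global die-off -- are not emitted.
#'
#' @param cube a \linkS4class{SpaceTimeCube}
#' @param delay phase-embedding delay (frames; default: quarter period)
#' @param persistence minimum number of frames a tip track must span to
#'   be emitted (default: one dominant rotation period -- a phase
#'   singularity only counts as a spiral tip once it has completed a
#'   full rotation, which is what distinguishes a rotor core from a
#'   transient wave-collision defect)
#' @param actThreshold,radiusR,windowW passed to
#'   \code{\link{detectTargetOrigins}}
#' @param maskRel amplitude mask level passed to
#'   \code{\link{phaseEmbed}}
#' @return an \linkS4class{EventPlot}
#' @export
buildEventPlot <- function(cube, delay = NULL, persistence = NULL,
                           actThreshold = NULL, radiusR = 10,
                           windowW = NULL, maskRel = 0.3) {
    d <- dim(frames(cube))
    if (is.null(persistence))
        persistence <- max(3L, as.integer(estimateDominantPeriod(cube)))
    ph <- phaseEmbed(cube, delay = delay, maskRel = maskRel)
    off <- attr(ph, "frameOffset")
    tipList <- vector("list", dim(ph)[3])
    for (k in seq_len(dim(ph)[3]))
        tipList[[k]] <- detectSpiralTips(ph[, , k], tFrame = k + off - 1)
    tips <- do.call(rbind, tipList)
    tips <- .persistentTips(tips, radius = 2, minFrames = persistence)
    origins <- detectTargetOrigins(cube, actThreshold = actThreshold,
                                   radiusR = radiusR, windowW = windowW)
    EventPlot(rbind(tips, origins), shape = d[1:2], nFrames = d[3])
}

#' Time-collapsed (top-down) view of an event plot
#'
#' Per-site event counts collapsed over time for one event kind
#' (sub-pixel events binned to the nearest site).
#'
#' @param ep an \linkS4class{EventPlot}
#' @param kind \code{"spiral_tip"} or \code{"target_origin"}
#' @return numeric matrix of per-site counts
#' @export
topDownView <- function(ep, kind = c("spiral_tip", "target_origin")) {
    kind <- match.arg(kind)
    sh <- latticeShape(ep)
    m <- matrix(0, sh[1], sh[2])
    ev <- events(ep)
    ev <- ev[ev$kind == kind, , drop = FALSE]
    if (nrow(ev) == 0) return(m)
    i <- pmin(pmax(round(ev$x) + 1, 1), sh[1])
    j <- pmin(pmax(round(ev$y) + 1, 1), sh[2])
    for (r in seq_along(i)) m[i[r], j[r]] <- m[i[r], j[r]] + 1
    m
}
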