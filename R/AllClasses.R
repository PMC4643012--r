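#' SpaceTimeCube: an ordered stack of lattice fields
#'
#' The universal movie container of the package: a three-dimensional array
#' holding one \code{nx x ny} field per recorded frame, together with the
#' recording interval \code{dtRecord} (model time units between stored
#' frames), the lattice spacing \code{dx} and provenance metadata (model
#' name, seed).  All simulators return their output in this form and all
#' event detectors consume it.
#'
#' @slot frames three-dimensional numeric array \code{[nx, ny, nt]}
#' @slot dtRecord time between stored frames (model time units)
#' @slot dx lattice spacing (dimensionless, default 1)
#' @slot modelName character tag of the producing model
#' @slot seed integer seed used for the run (\code{NA} if none)
#'
#' @export
setClass("SpaceTimeCube",
    representation(frames = "array", dtRecord = "numeric", dx = "numeric",
                   modelName = "character", seed = "integer"),
    prototype(dtRecord = 1, dx = 1, modelName = "", seed = NA_integer_))

setValidity("SpaceTimeCube", function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L)
        return("frames must be a 3-d array [nx, ny, nt]")
    if (d[1] < 3L || d[2] < 3L)
        return("lattice must be at least 3 x 3")
    if (d[3] < 1L)
        return("at least one frame is required")
    if (!all(is.finite(object@frames)))
        return("all frame values must be finite")
    if (length(object@dtRecord) != 1L || object@dtRecord <= 0)
        return("dtRecord must be a positive scalar")
    if (length(object@dx) != 1L || object@dx <= 0)
        return("dx must be a positive scalar")
    TRUE
})

#' Construct a SpaceTimeCube
#'
#' @param frames 3-d array \code{[nx, ny, nt]}, or a list of equally sized
#'   matrices (stacked along the time axis)
#' @param dtRecord time between stored frames
#' @param dx lattice spacing
#' @param modelName character tag
#' @param seed integer seed (optional)
#' @return a \linkS4class{SpaceTimeCube}
#' @export
SpaceTimeCube <- function(frames, dtRecord = 1, dx = 1, modelName = "",
                          seed = NA_integer_) {
    if (is.list(frames)) {
        stopifnot(length(frames) >= 1L)
        d <- dim(frames[[1L]])
        frames <- array(unlist(frames, use.names = FALSE),
                        dim = c(d, length(frames)))
    }
    if (is.integer(frames)) frames <- array(as.numeric(frames), dim(frames))
    new("SpaceTimeCube", frames = frames, dtRecord = dtRecord, dx = dx,
        modelName = modelName, seed = as.integer(seed))
}

#' CellPropertyMap: per-site fixed variability
#'
#' A per-site map of a quenched (time-constant) cell property: a
#' developmental-path time offset, an excitability parameter, or a
#' pacemaker mask.  This is the biological-variability input that the
#' ensemble statistics correlate with pattern-event maps.
#'
#' @slot values numeric \code{nx x ny} matrix
#' @slot kind one of \code{"excitability_c"}, \code{"time_offset"},
#'   \code{"pacemaker_mask"}
#' @export
setClass("CellPropertyMap",
    representation(values = "matrix", kind = "character"))

setValidity("CellPropertyMap", function(object) {
    ok <- c("excitability_c", "time_offset", "pacemaker_mask")
    if (!(length(object@kind) == 1L && object@kind %in% ok))
        return(sprintf("kind must be one of: %s", paste(ok, collapse = ", ")))
    if (!all(is.finite(object@values)))
        return("all values must be finite")
    if (object@kind == "time_offset" && any(object@values < 0))
        return("time offsets must be non-negative")
    if (object@kind == "pacemaker_mask" &&
        !all(object@values %in% c(0, 1, 2)))
        return("pacemaker mask values must be 0 (none), 1 (fixed) or 2 (extra)")
    TRUE
})

#' Construct a CellPropertyMap
#' @param values numeric matrix
#' @param kind property kind
#' @return a \linkS4class{CellPropertyMap}
#' @export
CellPropertyMap <- function(values,
                            kind = c("excitability_c", "time_offset",
                                     "pacemaker_mask")) {
    kind <- match.arg(kind)
    storage.mode(values) <- "double"
    new("CellPropertyMap", values = values, kind = kind)
}

#' EventPlot: the pattern-event representation of a movie
#'
#' Typed point events extracted from a spatiotemporal movie: target-wave
#' origins and chirality-resolved spiral tips, each at lattice coordinates
#' \code{(x, y)} (0-based, sub-pixel reals allowed) and frame index
#' \code{t}.  Events are kept sorted by \code{t}, then row-major.
#'
#' @slot events data.frame with columns \code{kind}, \code{chirality},
#'   \code{x}, \code{y}, \code{t}
#' @slot shape integer vector \code{c(nx, ny)}
#' @slot nFrames number of frames of the source movie
#' @export
setClass("EventPlot",
    representation(events = "data.frame", shape = "integer",
                   nFrames = "integer"))

setValidity("EventPlot", function(object) {
    ev <- object@events
    need <- c("kind", "chirality", "x", "y", "t")
    if (!all(need %in% names(ev)))
        return(sprintf("events must have columns: %s",
                       paste(need, collapse = ", ")))
    if (!all(ev$kind %in% c("target_origin", "spiral_tip")))
        return("kind must be target_origin or spiral_tip")
    if (!all(ev$chirality %in% c("left", "right", "none")))
        return("chirality must be left, right or none")
    bad <- (ev$kind == "target_origin") != (ev$chirality == "none")
    if (any(bad))
        return("chirality must be 'none' iff kind is target_origin")
    if (length(object@shape) != 2L)
        return("shape must be c(nx, ny)")
    if (nrow(ev) > 0) {
        if (any(ev$x < 0 | ev$x >= object@shape[1]) ||
            any(ev$y < 0 | ev$y >= object@shape[2]))
            return("event coordinates out of lattice range")
        o <- order(ev$t, ev$x, ev$y)
        if (any(o != seq_len(nrow(ev))))
            return("events must be sorted by t, then row-major")
    }
    TRUE
})

#' Construct an EventPlot (events are sorted on construction)
#' @param events data.frame with columns kind, chirality, x, y, t
#' @param shape lattice shape c(nx, ny)
#' @param nFrames number of frames in the source movie
#' @return an \linkS4class{EventPlot}
#' @export
EventPlot <- function(events = emptyEvents(), shape, nFrames) {
    events <- as.data.frame(events)
    if (nrow(events) > 0) {
        events <- events[order(events$t, events$x, events$y), , drop = FALSE]
        rownames(events) <- NULL
    }
    new("EventPlot", events = events, shape = as.integer(shape),
        nFrames = as.integer(nFrames))
}

#' An empty event table with the canonical columns
#' @return zero-row data.frame
#' @export
emptyEvents <- function() {
    data.frame(kind = character(0), chirality = character(0),
               x = numeric(0), y = numeric(0), t = numeric(0),
               stringsAsFactors = FALSE)
}

#' OccupancyMap: per-site event counts over an ensemble
#'
#' Accumulates how often an event kind occurred at each lattice site over
#' an ensemble of runs (the red-scale occupancy signal of ensemble
#' figures).
#'
#' @slot counts numeric matrix of non-negative per-site counts
#' @slot nRuns number of runs accumulated
#' @slot kind event kind counted
#' @export
setClass("OccupancyMap",
    representation(counts = "matrix", nRuns = "integer", kind = "character"))

setValidity("OccupancyMap", function(object) {
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (object@nRuns < 1L) return("nRuns must be >= 1")
    if (!(object@kind %in% c("target_origin", "spiral_tip")))
        return("kind must be target_origin or spiral_tip")
    TRUE
})
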