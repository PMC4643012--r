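#' @import methods
NULL

#' Frame stack of a SpaceTimeCube
#' @param x a SpaceTimeCube
#' @return 3-d numeric array [nx, ny, nt]
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
setMethod("frames", "SpaceTimeCube", function(x) x@frames)

#' Number of frames
#' @param x a SpaceTimeCube or EventPlot
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
setMethod("nFrames", "SpaceTimeCube", function(x) dim(x@frames)[3])

#' @rdname nFrames
setMethod("nFrames", "EventPlot", function(x) x@nFrames)

#' Recording interval (time between stored frames)
#' @param x a SpaceTimeCube
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname frameInterval
setMethod("frameInterval", "SpaceTimeCube", function(x) x@dtRecord)

#' Lattice spacing
#' @param x a SpaceTimeCube
#' @export
setGeneric("latticeSpacing", function(x) standardGeneric("latticeSpacing"))

#' @rdname latticeSpacing
setMethod("latticeSpacing", "SpaceTimeCube", function(x) x@dx)

#' Lattice shape c(nx, ny)
#' @param x a SpaceTimeCube, EventPlot, CellPropertyMap or OccupancyMap
#' @export
setGeneric("latticeShape", function(x) standardGeneric("latticeShape"))

#' @rdname latticeShape
setMethod("latticeShape", "SpaceTimeCube", function(x) dim(x@frames)[1:2])

#' @rdname latticeShape
setMethod("latticeShape", "EventPlot", function(x) x@shape)

#' @rdname latticeShape
setMethod("latticeShape", "CellPropertyMap", function(x) dim(x@values))

#' @rdname latticeShape
setMethod("latticeShape", "OccupancyMap", function(x) dim(x@counts))

#' Extract a single frame as a matrix
#' @param x a SpaceTimeCube
#' @param i frame index (1-based)
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname getFrame
setMethod("getFrame", "SpaceTimeCube", function(x, i) x@frames[, , i])

#' Per-site values of a property map
#' @param x a CellPropertyMap
#' @export
setGeneric("propertyValues", function(x) standardGeneric("propertyValues"))

#' @rdname propertyValues
setMethod("propertyValues", "CellPropertyMap", function(x) x@values)

#' Kind of a property map or occupancy map
#' @param x a CellPropertyMap or OccupancyMap
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))

#' @rdname mapKind
setMethod("mapKind", "CellPropertyMap", function(x) x@kind)

#' @rdname mapKind
setMethod("mapKind", "OccupancyMap", function(x) x@kind)

#' Event table of an EventPlot
#' @param x an EventPlot
#' @return data.frame with columns kind, chirality, x, y, t
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname events
setMethod("events", "EventPlot", function(x) x@events)

#' Per-site counts of an OccupancyMap
#' @param x an OccupancyMap
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname counts
setMethod("counts", "OccupancyMap", function(x) x@counts)

#' Number of runs accumulated in an OccupancyMap
#' @param x an OccupancyMap
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname nRuns
setMethod("nRuns", "OccupancyMap", function(x) x@nRuns)

setMethod("show", "SpaceTimeCube", function(object) {
    d <- dim(object@frames)
    cat(sprintf("SpaceTimeCube: %d x %d lattice, %d frames (dtRecord = %g, dx = %g)\n",
                d[1], d[2], d[3], object@dtRecord, object@dx))
    if (nzchar(object@modelName))
        cat(sprintf("  model: %s\n", object@modelName))
    if (!is.na(object@seed))
        cat(sprintf("  seed: %d\n", object@seed))
    r <- range(object@frames)
    cat(sprintf("  value range: [%.4g, %.4g]\n", r[1], r[2]))
})

setMethod("show", "CellPropertyMap", function(object) {
    d <- dim(object@values)
    cat(sprintf("CellPropertyMap (%s): %d x %d, range [%.4g, %.4g]\n",
                object@kind, d[1], d[2],
                min(object@values), max(object@values)))
})

setMethod("show", "EventPlot", function(object) {
    ev <- object@events
    cat(sprintf("EventPlot: %d x %d lattice, %d frames\n",
                object@shape[1], object@shape[2], object@nFrames))
    cat(sprintf("  %d target origins, %d spiral tips (%d left, %d right)\n",
                sum(ev$kind == "target_origin"),
                sum(ev$kind == "spiral_tip"),
                sum(ev$chirality == "left"),
                sum(ev$chirality == "right")))
})

setMethod("show", "OccupancyMap", function(object) {
    d <- dim(object@counts)
    cat(sprintf("OccupancyMap (%s): %d x %d, %d events over %d runs\n",
                object@kind, d[1], d[2], sum(object@counts), object@nRuns))
})
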