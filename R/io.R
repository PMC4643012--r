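#' Write a SpaceTimeCube as a multi-page 32-bit float TIFF
#'
#' One page per frame.  Page values are stored rescaled to [0, 1]; the
#' affine transform (offset, scale) and the cube metadata (dtRecord,
#' dx, model name, seed) go to a YAML sidecar \code{<path>.yml} so the
#' round trip is lossless to float32 precision.
#'
#' @param cube a \linkS4class{SpaceTimeCube}
#' @param path output TIFF path
#' @return \code{path}, invisibly
#' @export
writeCube <- function(cube, path) {
    arr <- frames(cube)
    lo <- min(arr); hi <- max(arr)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(k) (arr[, , k] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
    meta <- list(offset = lo, scale = scale, dtRecord = frameInterval(cube),
                 dx = latticeSpacing(cube), modelName = cube@modelName,
                 seed = if (is.na(cube@seed)) "NA" else cube@seed,
                 nx = dim(arr)[1], ny = dim(arr)[2], nt = dim(arr)[3])
    yaml::write_yaml(meta, paste0(path, ".yml"))
    invisible(path)
}

#' Read a SpaceTimeCube written by \code{\link{writeCube}}
#'
#' Plain multi-page TIFFs without a sidecar are read with identity
#' scaling and default metadata.
#'
#' @param path TIFF path
#' @return a \linkS4class{SpaceTimeCube}
#' @export
readCube <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    sidecar <- paste0(path, ".yml")
    meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else
        list(offset = 0, scale = 1, dtRecord = 1, dx = 1, modelName = "",
             seed = "NA")
    arr <- array(unlist(pages, use.names = FALSE),
                 dim = c(dim(pages[[1]]), length(pages)))
    arr <- arr * meta$scale + meta$offset
    SpaceTimeCube(arr, dtRecord = meta$dtRecord, dx = meta$dx,
                  modelName = meta$modelName,
                  seed = if (identical(meta$seed, "NA")) NA_integer_
                         else as.integer(meta$seed))
}

#' Write an EventPlot to CSV
#'
#' Columns: kind, chirality, x, y, t.  Shape and frame count go to a
#' header comment line.
#'
#' @param ep an \linkS4class{EventPlot}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeEvents <- function(ep, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# shape %d %d frames %d", ep@shape[1], ep@shape[2],
                       ep@nFrames), con)
    utils::write.csv(events(ep), con, row.names = FALSE)
    invisible(path)
}

#' Read an EventPlot written by \code{\link{writeEvents}}
#'
#' @param path CSV path
#' @param shape,nFrames lattice shape and frame count; taken from the
#'   header comment when present
#' @return an \linkS4class{EventPlot}
#' @export
readEvents <- function(path, shape = NULL, nFrames = NULL) {
    first <- readLines(path, n = 1)
    if (startsWith(first, "# shape")) {
        nums <- as.integer(strsplit(first, " +")[[1]][c(3, 4, 6)])
        if (is.null(shape)) shape <- nums[1:2]
        if (is.null(nFrames)) nFrames <- nums[3]
    }
    if (is.null(shape) || is.null(nFrames))
        stop("shape and nFrames must be given when the header is absent")
    ev <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
    if (nrow(ev) > 0) {
        bad <- which(!(ev$kind %in% c("target_origin", "spiral_tip")))
        if (length(bad) > 0)
            stop(sprintf("unknown event kind '%s' in row %d of %s",
                         ev$kind[bad[1]], bad[1], path))
    }
    EventPlot(ev, shape = shape, nFrames = nFrames)
}

#' Read a flat YAML-style run configuration
#' @param path YAML file path
#' @return named list
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' Write a flat run configuration as YAML
#' @param config named list
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}
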