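#' @useDynLib PatternEvents, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.bcCode <- function(bc = c("no_flux", "periodic")) {
    bc <- match.arg(bc)
    if (bc == "periodic") 1L else 0L
}

.checkField <- function(f, what = "field") {
    if (!is.matrix(f)) stop(sprintf("invalid %s: must be a matrix", what))
    if (nrow(f) < 3L || ncol(f) < 3L)
        stop(sprintf("invalid %s: lattice must be at least 3 x 3", what))
    if (!all(is.finite(f)))
        stop(sprintf("invalid %s: non-finite values", what))
    invisible(f)
}

#' Five-point discrete Laplacian
#'
#' \code{(f[i+1,j] + f[i-1,j] + f[i,j+1] + f[i,j-1] - 4 f[i,j]) / dx^2},
#' with boundary neighbours mirrored (\code{no_flux}, zero-gradient) or
#' wrapped (\code{periodic}).
#'
#' @param f numeric matrix (the lattice field)
#' @param dx lattice spacing
#' @param bc boundary condition, \code{"no_flux"} (default) or
#'   \code{"periodic"}
#' @return matrix of the same shape
#' @export
laplacian5pt <- function(f, dx = 1, bc = c("no_flux", "periodic")) {
    .checkField(f)
    laplacian5Cpp(f, dx, .bcCode(match.arg(bc)))
}

#' Eight-point discrete Laplacian (equal weights)
#'
#' Sum of all 8 neighbours minus 8 times the centre, normalised by
#' \code{dx^2}.  Boundary handling as in \code{\link{laplacian5pt}}.
#'
#' @inheritParams laplacian5pt
#' @return matrix of the same shape
#' @export
laplacian8pt <- function(f, dx = 1, bc = c("no_flux", "periodic")) {
    .checkField(f)
    laplacian8Cpp(f, dx, .bcCode(match.arg(bc)))
}

#' Generic forward-Euler integrator for lattice fields
#'
#' Explicit time stepping of an arbitrary model rule given as an R
#' function.  Intended for small problems and testing; the production
#' simulators use dedicated compiled kernels.
#'
#' @param state list of numeric matrices (the model fields)
#' @param rhs function \code{(state, t) -> list of derivative matrices}
#' @param dt time step (> 0)
#' @param nSteps number of steps (>= 1)
#' @param recordEvery record every this many steps (initial state is
#'   always recorded)
#' @param seed optional integer seed applied before stepping (for
#'   stochastic rules)
#' @param dx lattice spacing stored in the output
#' @return a \linkS4class{SpaceTimeCube} if the state has one field, else
#'   a list of cubes (one per field)
#' @export
integrateExplicit <- function(state, rhs, dt, nSteps, recordEvery = 1,
                              seed = NULL, dx = 1) {
    stopifnot(is.list(state), length(state) >= 1L, dt > 0, nSteps >= 1)
    if (!is.null(seed)) set.seed(seed)
    nf <- length(state)
    rec <- vector("list", nf)
    for (k in seq_len(nf)) rec[[k]] <- list(state[[k]])
    for (step in seq_len(nSteps)) {
        d <- rhs(state, (step - 1) * dt)
        for (k in seq_len(nf)) {
            state[[k]] <- state[[k]] + dt * d[[k]]
            if (!all(is.finite(state[[k]])))
                stop(sprintf("numerical blow-up at step %d (field %d)",
                             step, k))
        }
        if (step %% recordEvery == 0)
            for (k in seq_len(nf))
                rec[[k]][[length(rec[[k]]) + 1L]] <- state[[k]]
    }
    cubes <- lapply(rec, SpaceTimeCube, dtRecord = dt * recordEvery, dx = dx)
    if (nf == 1L) cubes[[1L]] else cubes
}
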