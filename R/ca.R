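#' CAGrid: state of the three-state excitable cellular automaton
#'
#' Each site is susceptible (S), excited (E) or refractory (R).  The
#' update rules are: S becomes E when at least one of its four von
#' Neumann neighbours is E; E always becomes R; R returns to S after
#' \code{r} steps.  \code{age} counts the steps a site has already spent
#' in the refractory state (0 for non-R sites).
#'
#' @slot states integer matrix with codes 0 = S, 1 = E, 2 = R
#' @slot age integer matrix, steps spent refractory (only meaningful for
#'   R sites, \code{0 <= age < r})
#' @slot r deterministic refractory period in steps (>= 1)
#' @export
setClass("CAGrid",
    representation(states = "matrix", age = "matrix", r = "integer"))

setValidity("CAGrid", function(object) {
    if (!all(object@states %in% c(0L, 1L, 2L)))
        return("states must be coded 0 (S), 1 (E), 2 (R)")
    if (object@r < 1L) return("r must be >= 1")
    if (!identical(dim(object@states), dim(object@age)))
        return("states and age must share shape")
    isR <- object@states == 2L
    if (any(object@age[!isR] != 0L))
        return("age must be 0 outside refractory sites")
    if (any(object@age[isR] < 0L) || any(object@age[isR] >= object@r))
        return("refractory age must satisfy 0 <= age < r")
    TRUE
})

#' Construct a CAGrid
#' @param states integer matrix coded 0 = S, 1 = E, 2 = R (or a character
#'   matrix of "S"/"E"/"R")
#' @param r refractory period in steps
#' @param age integer matrix of refractory ages (default all zero)
#' @return a \linkS4class{CAGrid}
#' @export
CAGrid <- function(states, r = 1L, age = NULL) {
    if (is.character(states)) {
        codes <- c(S = 0L, E = 1L, R = 2L)
        states <- matrix(codes[states], nrow(states), ncol(states))
    }
    storage.mode(states) <- "integer"
    if (is.null(age)) age <- matrix(0L, nrow(states), ncol(states))
    storage.mode(age) <- "integer"
    new("CAGrid", states = states, age = age, r = as.integer(r))
}

#' @rdname latticeShape
setMethod("latticeShape", "CAGrid", function(x) dim(x@states))

setMethod("show", "CAGrid", function(object) {
    d <- dim(object@states)
    cat(sprintf("CAGrid: %d x %d, r = %d; S: %d, E: %d, R: %d\n",
                d[1], d[2], object@r,
                sum(object@states == 0L), sum(object@states == 1L),
                sum(object@states == 2L)))
})

#' Per-site state codes of a CAGrid (0 = S, 1 = E, 2 = R)
#' @param g a CAGrid
#' @export
caStates <- function(g) g@states

# internal coding used by the compiled kernel: 0 = S, 1 = E,
# k in 2..r+1 = R with (k - 1) remaining refractory steps
.caEncode <- function(g) {
    m <- g@states
    isR <- m == 2L
    m[isR] <- (g@r - g@age[isR]) + 1L
    m
}

.caDecode <- function(m, r) {
    isR <- m >= 2L
    age <- matrix(0L, nrow(m), ncol(m))
    age[isR] <- r - (m[isR] - 1L)
    states <- m
    states[isR] <- 2L
    CAGrid(states, r = r, age = age)
}

#' One synchronous step of the deterministic automaton
#'
#' S -> E iff at least one of the 4 von Neumann neighbours is E; E -> R;
#' R -> S after \code{r} steps.  Sites outside the lattice contribute no
#' excitation.
#'
#' @param g a \linkS4class{CAGrid}
#' @return the updated \linkS4class{CAGrid}
#' @export
caStep <- function(g) {
    stopifnot(is(g, "CAGrid"))
    .caDecode(caStepCpp(.caEncode(g), g@r), g@r)
}

#' One synchronous step of the stochastic automaton
#'
#' As \code{\link{caStep}}, but a susceptible site with no excited
#' neighbour fires spontaneously with probability \code{f}, and a
#' refractory site recovers with probability \code{p} per step (the
#' deterministic clock is replaced by a geometric recovery time).
#'
#' @param g a \linkS4class{CAGrid} (ages are ignored in this variant)
#' @param f spontaneous excitation probability per site per step
#' @param p recovery probability R -> S per step
#' @param seed optional integer seed
#' @return the updated \linkS4class{CAGrid}
#' @export
caStepStochastic <- function(g, f, p, seed = NULL) {
    stopifnot(is(g, "CAGrid"), f >= 0, f <= 1, p >= 0, p <= 1)
    if (!is.null(seed)) set.seed(seed)
    m <- g@states
    out <- caStepStochasticCpp(m, f, p)
    CAGrid(out, r = g@r)
}

#' Open-wavefront initial condition
#'
#' A horizontal segment of excited sites of the given length with the
#' adjacent row below set refractory, all other sites susceptible.  This
#' is the classic initial condition whose open end curls up into a
#' rotating spiral, while a full-width (closed) front simply propagates
#' and annihilates at the boundary.
#'
#' @param nx,ny lattice dimensions
#' @param length number of excited sites in the front (< ny)
#' @param r refractory period
#' @param row row index of the excited layer (default: centre)
#' @param col starting column (default: centred segment)
#' @return a \linkS4class{CAGrid}
#' @export
caOpenWavefrontInit <- function(nx, ny, length, r = 1L, row = NULL,
                                col = NULL) {
    if (length <= 0) stop("front length must be positive")
    if (length > ny) stop("front length must not exceed ny")
    if (is.null(row)) row <- floor(nx / 2)
    if (is.null(col)) col <- max(1L, floor((ny - length) / 2) + 1L)
    states <- matrix(0L, nx, ny)
    cols <- col:(col + length - 1L)
    states[row, cols] <- 1L                      # excited layer
    if (row + 1L <= nx) states[row + 1L, cols] <- 2L  # refractory layer below
    CAGrid(states, r = r)
}

#' Run the cellular automaton and record a movie
#'
#' @param g a \linkS4class{CAGrid} initial state
#' @param nSteps number of steps
#' @param recordEvery record every this many steps
#' @param stochastic use the stochastic variant
#' @param f,p stochastic parameters (see \code{\link{caStepStochastic}})
#' @param seed integer seed (stochastic variant)
#' @return a \linkS4class{SpaceTimeCube} of state codes (S = 0, E = 1,
#'   R = 2)
#' @export
caSimulate <- function(g, nSteps, recordEvery = 1L, stochastic = FALSE,
                       f = 0, p = 1, seed = NULL) {
    stopifnot(is(g, "CAGrid"), nSteps >= 1)
    if (!stochastic) {
        cube <- caSimulateCpp(.caEncode(g), g@r, as.integer(nSteps),
                              as.integer(recordEvery))
        return(SpaceTimeCube(array(as.numeric(cube), dim(cube)),
                             dtRecord = recordEvery, modelName = "ca",
                             seed = if (is.null(seed)) NA_integer_ else seed))
    }
    if (!is.null(seed)) set.seed(seed)
    m <- g@states
    framesList <- list(m)
    for (step in seq_len(nSteps)) {
        m <- caStepStochasticCpp(m, f, p)
        if (step %% recordEvery == 0)
            framesList[[length(framesList) + 1L]] <- m
    }
    frames <- array(as.numeric(unlist(framesList, use.names = FALSE)),
                    dim = c(dim(m), length(framesList)))
    SpaceTimeCube(frames, dtRecord = recordEvery, modelName = "ca_stochastic",
                  seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Number of excited sites per frame of a CA movie
#' @param cube a \linkS4class{SpaceTimeCube} of CA state codes
#' @return numeric vector, one count per frame
#' @export
caExcitedCounts <- function(cube) {
    apply(frames(cube) == 1, 3, sum)
}
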