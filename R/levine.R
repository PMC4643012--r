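#' Parameters of the hybrid CA/ODE Dictyostelium model
#'
#' The model couples a discrete per-cell phase machine (ready, firing,
#' absolute refractory, relative refractory) to two continuous fields,
#' the extracellular cAMP concentration \code{c} and the excitability
#' \code{E}:
#' \deqn{\partial c/\partial t = -\Gamma c + r_F s + D \nabla^2 c}
#' \deqn{dE/dt = \eta + \beta c,}
#' with the eight-point Laplacian, \code{s = 1} while a cell fires, and
#' \code{E} capped at \code{eMax}.  A ready or relative-refractory cell
#' fires when \code{c} exceeds the phase-dependent threshold
#' \deqn{t(\tau) = [c_{max} - A \tau/(\tau + T_{ARP})](1 - E),\quad
#'       A = (T_{RRP} + T_{ARP})(c_{max} - c_{min})/T_{RRP}.}
#' Pacemakers fire spontaneously with probability \code{pF} per step.
#'
#' The printed sources fix only \code{beta}, \code{pF}, the pacemaker
#' fraction and the starting excitability per experiment; the remaining
#' constants here are reconstructed defaults chosen to support
#' propagating waves, wave break-up and spiral formation, and all
#' shipped analyses use only sign/shape properties robust to their
#' exact values.
#'
#' @param Gamma extracellular cAMP degradation rate
#' @param rF cAMP production rate while firing
#' @param D cAMP diffusion coefficient
#' @param eta intrinsic excitability increase
#' @param beta feedback factor (sensitivity amplification)
#' @param eMax excitability cap (<= 1)
#' @param cMax,cMin activation-threshold bounds (\code{cMax > cMin >= 0})
#' @param tARP,tRRP absolute/relative refractory durations
#' @param firingDuration time a cell spends in the firing state
#' @param pF pacemaker firing probability per time step
#' @param epsPM fraction of sites turned into (extra) pacemakers when a
#'   random layout is requested
#' @param dt integration time step
#' @param dx lattice spacing
#' @return a parameter list of class \code{"LevineParams"}
#' @export
levineParams <- function(Gamma = 1.0, rF = 0.05, D = 0.1, eta = 0,
                         beta = 0.2, eMax = 0.9, cMax = 0.1, cMin = 0.0025,
                         tARP = 2, tRRP = 8, firingDuration = 1, pF = 0.05,
                         epsPM = 0.195, dt = 0.1, dx = 1) {
    stopifnot(cMax > cMin, cMin >= 0, tARP > 0, tRRP > 0, pF >= 0, pF <= 1,
              dt > 0, firingDuration > 0, eMax <= 1)
    structure(list(Gamma = Gamma, rF = rF, D = D, eta = eta, beta = beta,
                   eMax = eMax, cMax = cMax, cMin = cMin, tARP = tARP,
                   tRRP = tRRP, firingDuration = firingDuration, pF = pF,
                   epsPM = epsPM, dt = dt, dx = dx),
              class = "LevineParams")
}

#' Phase-dependent activation threshold
#'
#' \code{[cMax - A tau/(tau + tARP)](1 - E)} with
#' \code{A = (tRRP + tARP)(cMax - cMin)/tRRP}; at \code{tau = 0} the
#' threshold is \code{cMax (1 - E)}, at \code{tau = tRRP} (and in the
#' ready state) it collapses to \code{cMin (1 - E)}.
#'
#' @param tau time since entering the relative refractory phase, in
#'   \code{[0, tRRP]} (vectorised)
#' @param E excitability in \code{[0, eMax]} (vectorised)
#' @param p a \code{\link{levineParams}} list
#' @return threshold value(s)
#' @export
levineThreshold <- function(tau, E, p = levineParams()) {
    if (any(tau < 0 | tau > p$tRRP))
        stop("tau must lie in [0, tRRP]")
    if (any(E < 0 | E > p$eMax))
        stop("E must lie in [0, eMax]")
    A <- (p$tRRP + p$tARP) * (p$cMax - p$cMin) / p$tRRP
    (p$cMax - A * tau / (tau + p$tARP)) * (1 - E)
}

#' One Euler step of the cAMP field
#'
#' \code{c + dt(-Gamma c + rF s + D lap8(c))} with the eight-point
#' Laplacian.
#'
#' @param c numeric matrix, extracellular cAMP field
#' @param s numeric matrix, firing indicator (1 while firing, else 0)
#' @param p a \code{\link{levineParams}} list
#' @param bc boundary condition
#' @return updated cAMP field
#' @export
campFieldStep <- function(c, s, p = levineParams(),
                          bc = c("no_flux", "periodic")) {
    bc <- match.arg(bc)
    stopifnot(identical(dim(c), dim(s)))
    out <- c + p$dt * (-p$Gamma * c + p$rF * s +
                       p$D * laplacian8pt(c, p$dx, bc))
    if (!all(is.finite(out))) stop("numerical blow-up in cAMP field step")
    out
}

#' One Euler step of the excitability field
#'
#' \code{E + (eta + beta c) dt}, clipped at \code{eMax}.
#'
#' @param E numeric matrix, excitability field
#' @param c numeric matrix, cAMP field
#' @param p a \code{\link{levineParams}} list
#' @return updated excitability field
#' @export
excitabilityStep <- function(E, c, p = levineParams()) {
    pmin(E + (p$eta + p$beta * c) * p$dt, p$eMax)
}

#' Update a single cell of the hybrid model (reference implementation)
#'
#' Pure-R single-cell phase machine used for unit testing the compiled
#' lattice kernel.  A cell is a list with elements \code{phase} (one of
#' \code{"ready"}, \code{"firing"}, \code{"absolute_refractory"},
#' \code{"relative_refractory"}), \code{tau} (time in phase),
#' \code{isPacemaker} and \code{E}.
#'
#' @param cell cell state list
#' @param cLocal local cAMP concentration
#' @param p a \code{\link{levineParams}} list
#' @param uPM uniform random number used for the pacemaker decision
#'   (supply for determinism; defaults to a fresh draw)
#' @return the updated cell state list
#' @export
levineCellUpdate <- function(cell, cLocal, p = levineParams(),
                             uPM = stats::runif(1)) {
    ph <- cell$phase; tau <- cell$tau + p$dt
    fire <- FALSE
    if (ph == "firing") {
        if (tau >= p$firingDuration) { ph <- "absolute_refractory"; tau <- 0 }
    } else if (ph == "absolute_refractory") {
        if (tau >= p$tARP) { ph <- "relative_refractory"; tau <- 0 }
    } else if (ph == "relative_refractory") {
        if (tau >= p$tRRP) {
            ph <- "ready"; tau <- 0
        } else if (cLocal > levineThreshold(tau, cell$E, p)) {
            fire <- TRUE
        }
    }
    if (ph == "ready") {
        if (cLocal > levineThreshold(p$tRRP, cell$E, p)) fire <- TRUE
        else if (isTRUE(cell$isPacemaker) && uPM < p$pF) fire <- TRUE
    }
    if (fire) { ph <- "firing"; tau <- 0 }
    cell$phase <- ph; cell$tau <- tau
    cell
}

#' Pacemaker layouts for ensemble experiments
#'
#' \code{"random"}: every site is independently a fixed pacemaker with
#' probability \code{fraction}.  \code{"clustered"}: the same expected
#' number of pacemakers grouped into two lateral bands separated by a
#' central pacemaker-free avenue of width \code{avenueWidth} (the
#' simple grouping whose ensemble tip occupancy concentrates in the
#' avenue).  \code{"fixed5"}: five fixed pacemakers at standard
#' positions, plus an extra random fraction \code{extraFraction} (coded
#' 2 in the mask and eligible for a start-up time disadvantage).
#'
#' @param nx,ny lattice size
#' @param kind layout kind
#' @param fraction pacemaker fraction for random/clustered layouts
#' @param avenueWidth width (columns) of the pacemaker-free central
#'   avenue in the clustered layout
#' @param extraFraction extra random-pacemaker fraction for
#'   \code{"fixed5"}
#' @param seed optional integer seed
#' @return a \linkS4class{CellPropertyMap} of kind
#'   \code{"pacemaker_mask"} (0 none, 1 fixed, 2 extra)
#' @export
pacemakerLayout <- function(nx, ny,
                            kind = c("random", "clustered", "fixed5"),
                            fraction = 0.19, avenueWidth = 16,
                            extraFraction = 0.001, seed = NULL) {
    kind <- match.arg(kind)
    if (!is.null(seed)) set.seed(seed)
    m <- matrix(0, nx, ny)
    if (kind == "random") {
        m[stats::runif(nx * ny) < fraction] <- 1
    } else if (kind == "clustered") {
        nPM <- round(fraction * nx * ny)
        half <- (ny - avenueWidth) %/% 2
        bandCols <- c(seq_len(half), (ny - half + 1):ny)
        eligible <- as.vector(outer(seq_len(nx), (bandCols - 1) * nx, `+`))
        m[sample(eligible, min(nPM, length(eligible)))] <- 1
    } else {
        pos <- rbind(c(0.25, 0.25), c(0.25, 0.75), c(0.75, 0.25),
                     c(0.75, 0.75), c(0.5, 0.5))
        ij <- cbind(pmax(1, round(pos[, 1] * nx)),
                    pmax(1, round(pos[, 2] * ny)))
        m[ij] <- 1
        extra <- stats::runif(nx * ny) < extraFraction & m == 0
        m[extra] <- 2
    }
    CellPropertyMap(m, kind = "pacemaker_mask")
}

#' Simulate the hybrid CA/ODE Dictyostelium model
#'
#' @param pmMask \linkS4class{CellPropertyMap} of kind
#'   \code{"pacemaker_mask"} (0 none, 1 fixed, 2 extra; extra pacemakers
#'   stay silent for the first \code{extraDisableT} time units, the time
#'   advantage of the fixed set)
#' @param p a \code{\link{levineParams}} list
#' @param T total simulation time
#' @param recordEvery record every this many steps
#' @param seed integer seed (pacemaker firing is stochastic)
#' @param E0 starting excitability (e.g. \code{eMax/2} or 0)
#' @param extraDisableT silence time for extra pacemakers (default 10\%
#'   of the run)
#' @param bc boundary condition
#' @param returnE also return the final excitability field
#' @return a \linkS4class{SpaceTimeCube} of the cAMP field (with the
#'   final excitability matrix in \code{attr(, "E")} when requested)
#' @export
levineSimulate <- function(pmMask, p = levineParams(), T = 200,
                           recordEvery = NULL, seed = NULL, E0 = 0,
                           extraDisableT = NULL,
                           bc = c("no_flux", "periodic"),
                           returnE = FALSE) {
    bc <- match.arg(bc)
    stopifnot(is(pmMask, "CellPropertyMap"),
              mapKind(pmMask) == "pacemaker_mask")
    if (!is.null(seed)) set.seed(seed)
    nSteps <- round(T / p$dt)
    if (is.null(recordEvery)) recordEvery <- max(1L, round(1 / p$dt))
    if (is.null(extraDisableT)) extraDisableT <- 0.1 * T
    pm <- propertyValues(pmMask)
    storage.mode(pm) <- "integer"
    res <- levineSimCpp(pm, p$Gamma, p$rF, p$D, p$eta, p$beta, p$eMax,
                        p$cMax, p$cMin, p$tARP, p$tRRP, p$firingDuration,
                        p$pF, E0, p$dx, p$dt, as.integer(nSteps),
                        as.integer(recordEvery),
                        as.integer(round(extraDisableT / p$dt)),
                        .bcCode(bc))
    cube <- SpaceTimeCube(res$cube, dtRecord = p$dt * recordEvery,
                          dx = p$dx, modelName = "levine",
                          seed = if (is.null(seed)) NA_integer_ else seed)
    if (returnE) attr(cube, "E") <- res$E
    cube
}
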