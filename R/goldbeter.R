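#' Parameters of the reduced three-variable cAMP relay model
#'
#' Reduced Martiel-Goldbeter model of Dictyostelium cAMP signalling.
#' Dynamic variables: fraction of active cAMP receptor \code{rho},
#' normalised intracellular cAMP \code{beta} and normalised
#' extracellular cAMP \code{gamma}:
#' \deqn{d\rho/dt = -f_1(\gamma)\rho + f_2(\gamma)(1 - \rho)}
#' \deqn{d\beta/dt = q \sigma \Phi(\rho, \gamma, \alpha) - (k_i + k_t)\beta}
#' \deqn{\partial\gamma/\partial t = k_t \beta / h - k_e \gamma
#'       + D_\gamma \nabla^2 \gamma}
#' with
#' \deqn{f_1 = (k_1 + k_2\gamma)/(1 + \gamma),\quad
#'       f_2 = (k_1 L_1 + k_2 L_2 c \gamma)/(1 + c\gamma)}
#' \deqn{\Phi = \alpha(\lambda\theta + \epsilon Y^2) /
#'       (1 + \alpha + \epsilon Y^2 (1 + \alpha)),\quad
#'       Y = \rho\gamma/(1 + \gamma).}
#' Times are in minutes.  The kinetic constants are the standard
#' reduced-model literature values; \code{sigma} (adenylate cyclase
#' activity) and \code{ke} (extracellular phosphodiesterase) are the two
#' parameters moved by the developmental path.
#'
#' @param k1,k2 receptor modification rates (1/min)
#' @param L1,L2,cr equilibrium/affinity constants (\code{cr} is the
#'   \code{c} inside \code{f2})
#' @param q,lambda,theta,epsY,alpha synthesis-function constants
#'   (\code{alpha} = normalised ATP)
#' @param ki,kt intracellular cAMP hydrolysis/transport rates (1/min)
#' @param h dilution factor
#' @param sigma adenylate cyclase activity (1/min)
#' @param ke extracellular hydrolysis rate (1/min)
#' @param Dg extracellular cAMP diffusion coefficient (sites^2/min)
#' @param dt integration step (min)
#' @param dx lattice spacing
#' @return a parameter list of class \code{"GoldbeterParams"}
#' @export
goldbeterParams <- function(k1 = 0.036, k2 = 0.666, L1 = 10, L2 = 0.005,
                            cr = 10, q = 4000, lambda = 0.01, theta = 0.01,
                            epsY = 1, alpha = 3, ki = 1.7, kt = 0.9, h = 5,
                            sigma = 0.55, ke = 5.4, Dg = 0.1, dt = 0.005,
                            dx = 1) {
    stopifnot(h > 0, dt > 0, all(c(k1, k2, L1, L2, cr, q, ki, kt, Dg) >= 0))
    structure(list(k1 = k1, k2 = k2, L1 = L1, L2 = L2, cr = cr, q = q,
                   lambda = lambda, theta = theta, epsY = epsY,
                   alpha = alpha, ki = ki, kt = kt, h = h, sigma = sigma,
                   ke = ke, Dg = Dg, dt = dt, dx = dx),
              class = "GoldbeterParams")
}

#' Developmental-path parameters for sigma and k_e
#'
#' Both parameters follow shifted sigmoids of global time \code{t} with a
#' shared per-site time offset:
#' \deqn{\sigma(t) = \sigma_{av} + \sigma_{amp}
#'       \tanh[(t - t_\sigma + \Delta t)/T_\sigma]}
#' \deqn{k_e(t) = k_{av} + k_{amp} \tanh[(t - t_k + \Delta t)/T_k].}
#' Offsets are exponential with mean \code{Delta} (the desynchronisation
#' parameter).  The default path constants are reconstructed so that a
#' single element traverses, in order, the steady, excitable,
#' oscillatory and excitable regimes.
#'
#' @param sigma_av,sigma_amp centre and amplitude of the sigma sigmoid
#' @param t_sigma,T_sigma centre time and width of the sigma sigmoid
#' @param k_av,k_amp centre and amplitude of the k_e sigmoid
#' @param t_k,T_k centre time and width of the k_e sigmoid
#' @param Delta mean of the exponential time-offset distribution (min)
#' @return a parameter list of class \code{"GBPathParams"}
#' @export
gbPathParams <- function(sigma_av = 0.55, sigma_amp = 0.4,
                         t_sigma = 80, T_sigma = 40,
                         k_av = 4.0, k_amp = 2.0,
                         t_k = 170, T_k = 35, Delta = 25) {
    stopifnot(T_sigma > 0, T_k > 0, Delta > 0)
    structure(list(sigma_av = sigma_av, sigma_amp = sigma_amp,
                   t_sigma = t_sigma, T_sigma = T_sigma, k_av = k_av,
                   k_amp = k_amp, t_k = t_k, T_k = T_k, Delta = Delta),
              class = "GBPathParams")
}

#' Receptor modification rates f1, f2
#'
#' @param gammaE extracellular cAMP (scalar or vector, >= 0)
#' @param p a \code{\link{goldbeterParams}} list
#' @return list with components \code{f1}, \code{f2}
#' @export
receptorRates <- function(gammaE, p = goldbeterParams()) {
    if (any(gammaE < 0)) stop("gamma must be non-negative")
    list(f1 = (p$k1 + p$k2 * gammaE) / (1 + gammaE),
         f2 = (p$k1 * p$L1 + p$k2 * p$L2 * p$cr * gammaE) /
              (1 + p$cr * gammaE))
}

#' cAMP synthesis function Phi
#'
#' @param rho fraction of active receptor in [0, 1]
#' @param gammaE extracellular cAMP (>= 0)
#' @param p a \code{\link{goldbeterParams}} list
#' @return Phi value(s)
#' @export
synthesisPhi <- function(rho, gammaE, p = goldbeterParams()) {
    Y <- rho * gammaE / (1 + gammaE)
    eY2 <- p$epsY * Y^2
    p$alpha * (p$lambda * p$theta + eY2) /
        (1 + p$alpha + eY2 * (1 + p$alpha))
}

#' Full right-hand side of the lattice model
#'
#' @param state list with matrices \code{rho}, \code{beta}, \code{gamma}
#' @param sigmaField per-site sigma (matrix or scalar)
#' @param keField per-site k_e (matrix or scalar)
#' @param p a \code{\link{goldbeterParams}} list
#' @param bc boundary condition for the gamma diffusion term
#' @return list with derivative matrices \code{drho}, \code{dbeta},
#'   \code{dgamma}
#' @export
goldbeterRHS <- function(state, sigmaField, keField, p = goldbeterParams(),
                         bc = c("no_flux", "periodic")) {
    bc <- match.arg(bc)
    rho <- state$rho; beta <- state$beta; gamma <- state$gamma
    fr <- receptorRates(gamma, p)
    phi <- synthesisPhi(rho, gamma, p)
    dgamma <- p$kt * beta / p$h - keField * gamma
    if (is.matrix(gamma) && p$Dg > 0)
        dgamma <- dgamma + p$Dg * laplacian5pt(gamma, p$dx, bc)
    list(drho = -fr$f1 * rho + fr$f2 * (1 - rho),
         dbeta = p$q * sigmaField * phi - (p$ki + p$kt) * beta,
         dgamma = dgamma)
}

#' Developmental-path values of (sigma, k_e)
#'
#' @param t global time (scalar or vector)
#' @param dtOffset per-site time offset (scalar or same shape as t)
#' @param pp a \code{\link{gbPathParams}} list
#' @return list with components \code{sigma}, \code{ke}
#' @export
gbPath <- function(t, dtOffset = 0, pp = gbPathParams()) {
    list(sigma = pp$sigma_av +
             pp$sigma_amp * tanh((t - pp$t_sigma + dtOffset) / pp$T_sigma),
         ke = pp$k_av + pp$k_amp * tanh((t - pp$t_k + dtOffset) / pp$T_k))
}

# single well-mixed element trajectory (deSolve, D = 0)
.gbElementRun <- function(y0, sigma, ke, p, T, dt = 0.02) {
    f <- function(t, y, parms) {
        fr <- receptorRates(max(y[3], 0), p)
        phi <- synthesisPhi(min(max(y[1], 0), 1), max(y[3], 0), p)
        list(c(-fr$f1 * y[1] + fr$f2 * (1 - y[1]),
               p$q * sigma * phi - (p$ki + p$kt) * y[2],
               p$kt * y[2] / p$h - ke * y[3]))
    }
    out <- deSolve::ode(y0, seq(0, T, by = dt), f, NULL, method = "lsoda")
    list(t = out[, 1], rho = out[, 2], beta = out[, 3], gamma = out[, 4])
}

#' Rest state of a single element at fixed (sigma, k_e)
#'
#' Found by relaxation from the receptor equilibrium at zero cAMP.
#'
#' @param sigma,ke parameter values
#' @param p a \code{\link{goldbeterParams}} list
#' @param T relaxation horizon (min)
#' @return named vector \code{c(rho, beta, gamma)}
#' @export
gbRestState <- function(sigma, ke, p = goldbeterParams(), T = 120) {
    y0 <- c(rho = p$L1 / (1 + p$L1), beta = 0, gamma = 0)
    tr <- .gbElementRun(y0, sigma, ke, p, T)
    n <- length(tr$t)
    c(rho = tr$rho[n], beta = tr$beta[n], gamma = tr$gamma[n])
}

#' Classify the dynamical regime of a single element
#'
#' \emph{Oscillatory}: the gamma oscillation amplitude after the
#' transient exceeds \code{1e-3}.  \emph{Excitable}: stable rest, and an
#' additive gamma pulse of twice the rest value -- but no smaller than
#' \code{pulseFloor}, the physiological scale of a suprathreshold cAMP
#' pulse in normalised units (the rest concentration itself vanishes
#' deep in the quiescent region, so a pure multiple of it cannot probe
#' relay competence) -- triggers a beta excursion larger than five
#' times the pulse size.  Otherwise \emph{steady}.  Labels are
#' deterministic given \code{(sigma, ke, p)}.
#'
#' @param sigma,ke parameter values
#' @param p a \code{\link{goldbeterParams}} list
#' @param T observation horizon per stage (min)
#' @param pulseFloor minimum probe pulse amplitude (normalised gamma)
#' @return one of \code{"steady"}, \code{"excitable"},
#'   \code{"oscillatory"}
#' @export
gbClassifyRegime <- function(sigma, ke, p = goldbeterParams(), T = 120,
                             pulseFloor = 0.05) {
    if (sigma <= 0) return("steady")
    y0 <- c(rho = p$L1 / (1 + p$L1), beta = 0, gamma = 0)
    tr <- .gbElementRun(y0, sigma, ke, p, 2 * T)
    late <- tr$gamma[tr$t > T]
    if (max(late) - min(late) > 1e-3) return("oscillatory")
    n <- length(tr$t)
    rest <- c(rho = tr$rho[n], beta = tr$beta[n], gamma = tr$gamma[n])
    pulse <- max(2 * rest["gamma"], pulseFloor)
    if (pulse <= 0) return("steady")
    y1 <- rest + c(0, 0, pulse)
    tr2 <- .gbElementRun(y1, sigma, ke, p, min(T, 60))
    if (max(tr2$beta) - rest["beta"] > 5 * pulse) "excitable" else "steady"
}

#' Regime labels along the developmental path
#'
#' Classifies the regime of an element at a set of path positions
#' \code{s = t + Delta t} (global time plus offset).  Used both for the
#' regime-sequence diagnostic and, via a shared lookup, for
#' effective-pacemaker identification.
#'
#' @param s vector of path positions (min)
#' @param pp a \code{\link{gbPathParams}} list
#' @param p a \code{\link{goldbeterParams}} list
#' @return character vector of regime labels along \code{s}
#' @export
gbPathRegimes <- function(s, pp = gbPathParams(), p = goldbeterParams()) {
    key <- paste(c(unlist(pp), unlist(p)), collapse = "|")
    cache <- .gbRegimeCache
    if (is.null(cache[[key]])) cache[[key]] <- list(s = numeric(0),
                                                   r = character(0))
    known <- match(round(s, 6), round(cache[[key]]$s, 6))
    out <- character(length(s))
    out[!is.na(known)] <- cache[[key]]$r[known[!is.na(known)]]
    todo <- which(is.na(known))
    if (length(todo) > 0) {
        fresh <- vapply(s[todo], function(si) {
            pt <- gbPath(si, 0, pp)
            gbClassifyRegime(pt$sigma, pt$ke, p)
        }, character(1))
        out[todo] <- fresh
        cache[[key]]$s <- c(cache[[key]]$s, s[todo])
        cache[[key]]$r <- c(cache[[key]]$r, fresh)
    }
    out
}

# session cache for single-element regime labels along the path (the
# classification is deterministic and expensive)
.gbRegimeCache <- new.env(parent = emptyenv())

#' Identify effective pacemaker sites
#'
#' Effective pacemakers are the cells still in the oscillatory regime
#' when the majority of cells has already reached the excitable regime:
#' sites whose time offset lies in the top \code{qFrac} quantile
#' \emph{and} which classify as oscillatory at the first global time at
#' which excitable is the majority regime.  Ties are broken by larger
#' offset, then row-major order.
#'
#' @param offsets \linkS4class{CellPropertyMap} of kind
#'   \code{"time_offset"}
#' @param pp a \code{\link{gbPathParams}} list
#' @param p a \code{\link{goldbeterParams}} list
#' @param qFrac fraction of sites eligible (0 < qFrac <= 1)
#' @param tGrid global times scanned for the excitable-majority crossing
#' @param sGridN resolution of the path-position classification lookup
#' @return logical matrix marking effective pacemaker sites, with the
#'   crossing time in \code{attr(, "tMajority")}
#' @export
effectivePacemakers <- function(offsets, pp = gbPathParams(),
                                p = goldbeterParams(), qFrac = 0.05,
                                tGrid = NULL, sGridN = 120) {
    stopifnot(qFrac > 0, qFrac <= 1, is(offsets, "CellPropertyMap"),
              mapKind(offsets) == "time_offset")
    off <- propertyValues(offsets)
    n <- length(off)
    if (max(off) - min(off) < 1e-12)
        warning("degenerate offsets (all equal): mask from tie-break only")
    if (is.null(tGrid))
        tGrid <- seq(0, pp$t_k + 4 * pp$T_k, length.out = 80)
    # regime depends on (t + offset) only: classify once along a 1-d grid
    sMin <- min(tGrid) + min(off); sMax <- max(tGrid) + max(off)
    step <- max(1, ceiling((sMax - sMin) / sGridN))
    sGrid <- seq(floor(sMin / step) * step, ceiling(sMax / step) * step,
                 by = step)
    reg <- gbPathRegimes(sGrid, pp, p)
    lookup <- function(s) reg[pmin(pmax(findInterval(s, sGrid), 1L),
                                   length(sGrid))]
    tMaj <- NA_real_
    for (t in tGrid) {
        if (mean(lookup(t + off) == "excitable") > 0.5) { tMaj <- t; break }
    }
    if (is.na(tMaj)) tMaj <- tGrid[length(tGrid)]
    k <- max(1L, round(qFrac * n))
    ord <- order(-off, seq_len(n))          # larger offset first, then row-major
    topq <- logical(n); topq[ord[seq_len(k)]] <- TRUE
    osc <- lookup(tMaj + off) == "oscillatory"
    mask <- matrix(topq & osc, nrow(off), ncol(off))
    attr(mask, "tMajority") <- tMaj
    mask
}

#' Simulate the cAMP relay model on a lattice
#'
#' All sites start from the receptor equilibrium at zero cAMP; per-site
#' \code{(sigma, ke)} follow the developmental path with the supplied
#' time offsets.  Optionally a set of fixed pacemaker sites receives a
#' bonus offset (a time advantage on the path).
#'
#' @param offsets \linkS4class{CellPropertyMap} of kind
#'   \code{"time_offset"}
#' @param pp a \code{\link{gbPathParams}} list
#' @param p a \code{\link{goldbeterParams}} list
#' @param T total simulated time (min)
#' @param recordEvery record every this many steps
#' @param fixedSites optional two-column matrix of (row, col) indices of
#'   fixed pacemaker sites
#' @param bonusOffset extra offset added at \code{fixedSites} (min)
#' @param bc boundary condition
#' @return a \linkS4class{SpaceTimeCube} of extracellular cAMP
#'   \code{gamma}
#' @export
goldbeterSimulate <- function(offsets, pp = gbPathParams(),
                              p = goldbeterParams(), T = 220,
                              recordEvery = NULL, fixedSites = NULL,
                              bonusOffset = 0,
                              bc = c("no_flux", "periodic")) {
    bc <- match.arg(bc)
    stopifnot(is(offsets, "CellPropertyMap"),
              mapKind(offsets) == "time_offset")
    off <- propertyValues(offsets)
    if (!is.null(fixedSites))
        off[fixedSites] <- off[fixedSites] + bonusOffset
    nx <- nrow(off); ny <- ncol(off)
    nSteps <- round(T / p$dt)
    if (is.null(recordEvery)) recordEvery <- max(1L, round(0.5 / p$dt))
    pathUpdate <- max(1L, round(0.5 / p$dt))
    rho0 <- matrix(p$L1 / (1 + p$L1), nx, ny)
    beta0 <- matrix(0, nx, ny)
    g0 <- matrix(0, nx, ny)
    cube <- goldbeterSimCpp(rho0, beta0, g0, off,
                            p$k1, p$k2, p$L1, p$L2, p$cr, p$q, p$ki, p$kt,
                            p$h, p$lambda, p$theta, p$epsY, p$alpha,
                            pp$sigma_av, pp$sigma_amp, pp$t_sigma,
                            pp$T_sigma, pp$k_av, pp$k_amp, pp$t_k, pp$T_k,
                            p$Dg, p$dx, p$dt, as.integer(nSteps),
                            as.integer(recordEvery), as.integer(pathUpdate),
                            .bcCode(bc))
    SpaceTimeCube(cube, dtRecord = p$dt * recordEvery, dx = p$dx,
                  modelName = "goldbeter")
}
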