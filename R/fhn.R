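#' FitzHugh-Nagumo lattice parameters
#'
#' Kinetics of the diffusively coupled FitzHugh-Nagumo lattice
#' \deqn{du/dt = (1/\epsilon)((a - u)(u - 1)u - v) + D \nabla^2 u}
#' \deqn{dv/dt = b u - \gamma v + c_{ij}(t)}
#' where \code{u} is the voltage-like variable, \code{v} the recovery
#' variable and \code{c} the excitability parameter subject to
#' variability.  Defaults: \code{a = -1}, \code{b = gamma = 0.12},
#' \code{eps = 1}, \code{D = 0.1}, \code{dx = 1}.
#'
#' @param a,b,gamma,eps kinetic constants (\code{eps > 0})
#' @param D diffusion coefficient (>= 0)
#' @param dx lattice spacing
#' @return a parameter list of class \code{"FHNParams"}
#' @export
fhnParams <- function(a = -1, b = 0.12, gamma = 0.12, eps = 1, D = 0.1,
                      dx = 1) {
    stopifnot(eps > 0, D >= 0, dx > 0)
    structure(list(a = a, b = b, gamma = gamma, eps = eps, D = D, dx = dx),
              class = "FHNParams")
}

#' Developmental-path parameters for the FHN excitability c
#'
#' The path carries every element's \code{c} sigmoidally from
#' \code{-c0} to \code{+c0}:
#' \deqn{c_{ij}(t) = c_0 \tanh[(t - t_c + \Delta t_{ij})/T_c].}
#'
#' @param c0 path amplitude (default 0.02)
#' @param tc path centre time (default 1000)
#' @param Tc path width (> 0, default 50)
#' @return a parameter list of class \code{"FHNPathParams"}
#' @export
fhnPathParams <- function(c0 = 0.02, tc = 1000, Tc = 50) {
    stopifnot(Tc > 0)
    structure(list(c0 = c0, tc = tc, Tc = Tc), class = "FHNPathParams")
}

#' FHN right-hand side (reaction plus five-point diffusion)
#'
#' @param u,v numeric matrices (voltage-like and recovery fields)
#' @param c numeric matrix or scalar (per-site excitability parameter)
#' @param p a \code{\link{fhnParams}} list
#' @param bc boundary condition for the diffusion term
#' @return list with derivative matrices \code{du}, \code{dv}
#' @export
fhnRHS <- function(u, v, c, p = fhnParams(), bc = c("no_flux", "periodic")) {
    bc <- match.arg(bc)
    stopifnot(identical(dim(u), dim(v)))
    if (is.matrix(c)) stopifnot(identical(dim(c), dim(u)))
    du <- (1 / p$eps) * ((p$a - u) * (u - 1) * u - v)
    if (p$D > 0) du <- du + p$D * laplacian5pt(u, p$dx, bc)
    dv <- p$b * u - p$gamma * v + c
    list(du = du, dv = dv)
}

#' Excitability parameter along the developmental path
#'
#' @param t global time (scalar or vector)
#' @param dtOffset per-element time offset \code{Delta t} (>= 0)
#' @param pp a \code{\link{fhnPathParams}} list
#' @return \code{c0 * tanh((t - tc + dtOffset)/Tc)}
#' @export
fhnPathC <- function(t, dtOffset = 0, pp = fhnPathParams()) {
    pp$c0 * tanh((t - pp$tc + dtOffset) / pp$Tc)
}

#' Sample exponential developmental-path time offsets
#'
#' One i.i.d. exponential draw with mean \code{Delta} per lattice site.
#' \code{Delta} is the desynchronisation parameter controlling the
#' spread of the elements along the path.
#'
#' @param nx,ny lattice size
#' @param Delta mean time offset (> 0)
#' @param seed optional integer seed
#' @return a \linkS4class{CellPropertyMap} of kind \code{"time_offset"}
#' @export
sampleTimeOffsets <- function(nx, ny, Delta, seed = NULL) {
    if (Delta <= 0) stop("Delta must be positive")
    if (!is.null(seed)) set.seed(seed)
    CellPropertyMap(matrix(stats::rexp(nx * ny, rate = 1 / Delta), nx, ny),
                    kind = "time_offset")
}

#' Rest state of a single uncoupled FHN element
#'
#' Solves the cubic fixed-point condition
#' \eqn{\gamma(a - u)(u - 1)u - b u - c = 0} and selects the real root
#' continuously connected to the rest state at the start of the
#' developmental path (for the default parameters the root is unique:
#' \eqn{u^* = (-c/\gamma)^{1/3}}).
#'
#' @param c excitability parameter value
#' @param p a \code{\link{fhnParams}} list
#' @return named vector \code{c(u, v)}
#' @export
fhnRestState <- function(c, p = fhnParams()) {
    # gamma * (-u^3 + (a+1) u^2 - a u) - b u - c = 0
    co <- c(-c, -(p$gamma * p$a + p$b), p$gamma * (p$a + 1), -p$gamma)
    rts <- polyroot(co)
    real <- Re(rts[abs(Im(rts)) < 1e-8])
    if (length(real) == 0) stop("no real fixed point found")
    guess <- sign(-c) * abs(c / p$gamma)^(1 / 3)
    u <- real[which.min(abs(real - guess))]
    v <- (p$b * u + c) / p$gamma
    c(u = u, v = v)
}

# single-element FHN trajectory by forward integration (deSolve)
.fhnElementRun <- function(u0, v0, c, p, T, dt = 0.05) {
    f <- function(t, y, parms) {
        list(c((1 / p$eps) * ((p$a - y[1]) * (y[1] - 1) * y[1] - y[2]),
               p$b * y[1] - p$gamma * y[2] + c))
    }
    times <- seq(0, T, by = dt)
    out <- deSolve::ode(c(u = u0, v = v0), times, f, NULL, method = "ode45")
    list(t = out[, 1], u = out[, 2], v = out[, 3])
}

#' Classify the dynamical regime of a single FHN element
#'
#' An uncoupled element is \emph{oscillatory} when its fixed point is
#' linearly unstable (sustained limit cycle confirmed by integration),
#' \emph{excitable} when the fixed point is stable but a standardised
#' suprathreshold kick (\code{u -> u + 0.5} from rest) produces a spike
#' with \code{u} exceeding 0.5 before returning, and \emph{steady}
#' otherwise.
#'
#' @param cValue excitability parameter of the element
#' @param p a \code{\link{fhnParams}} list (\code{D} is ignored)
#' @param T integration horizon used for confirmation runs
#' @return one of \code{"oscillatory"}, \code{"excitable"},
#'   \code{"steady"}
#' @export
fhnClassifyRegime <- function(cValue, p = fhnParams(), T = 2000) {
    fp <- fhnRestState(cValue, p)
    # Jacobian of the reaction kinetics at the fixed point
    u <- fp["u"]
    dcube <- -3 * u^2 + 2 * (p$a + 1) * u - p$a
    J <- matrix(c(dcube / p$eps, p$b, -1 / p$eps, -p$gamma), 2, 2)
    unstable <- max(Re(eigen(J, only.values = TRUE)$values)) > 1e-9
    if (unstable) {
        # confirm a sustained limit cycle from a small perturbation
        tr <- .fhnElementRun(fp["u"] + 0.01, fp["v"], cValue, p, T)
        late <- tr$u[tr$t > T / 2]
        if (max(late) - min(late) > 1e-3) return("oscillatory")
    }
    # stable rest: probe with the standardised kick
    tr <- .fhnElementRun(fp["u"] + 0.5, fp["v"], cValue, p, min(T, 500))
    if (max(tr$u) > 0.5) "excitable" else "steady"
}

#' Oscillation frequency of a single FHN element
#'
#' Frequency measured as the number of upward zero crossings of
#' \code{u - u_mid} per unit time in the second half of the run, where
#' \code{u_mid} is the mid-range of the late trajectory.  Returns 0 for
#' non-oscillating elements.
#'
#' @inheritParams fhnClassifyRegime
#' @return oscillation frequency (cycles per time unit)
#' @export
fhnOscillationFrequency <- function(cValue, p = fhnParams(), T = 2000) {
    fp <- fhnRestState(cValue, p)
    tr <- .fhnElementRun(fp["u"] + 0.01, fp["v"], cValue, p, T)
    sel <- tr$t > T / 2
    u <- tr$u[sel]; tt <- tr$t[sel]
    if (max(u) - min(u) < 1e-3) return(0)
    mid <- (max(u) + min(u)) / 2
    s <- u > mid
    ups <- which(!s[-length(s)] & s[-1])
    if (length(ups) < 2) return(0)
    (length(ups) - 1) / (tt[ups[length(ups)]] - tt[ups[1]])
}

#' Simulate the FHN lattice (static or developmental-path variability)
#'
#' In static mode each site keeps the fixed excitability from
#' \code{cmap}; in path mode (both \code{offsets} and \code{pathParams}
#' supplied) every site's \code{c} follows the sigmoid path with its own
#' time offset.  The lattice starts at the per-site rest state for the
#' initial \code{c}, optionally perturbed.
#'
#' @param p a \code{\link{fhnParams}} list
#' @param cmap \linkS4class{CellPropertyMap} of kind
#'   \code{"excitability_c"} (static mode)
#' @param offsets \linkS4class{CellPropertyMap} of kind
#'   \code{"time_offset"} (path mode)
#' @param pathParams a \code{\link{fhnPathParams}} list (path mode)
#' @param T total integration time
#' @param dt time step
#' @param recordEvery record every this many steps
#' @param seed integer seed for the initial perturbation
#' @param init initial condition: \code{"rest"} (per-site rest state),
#'   \code{"spiral"} (crossed-gradient protocol that seeds a single
#'   rotating spiral), or \code{"pulse"} (central suprathreshold kick)
#' @param noiseAmp amplitude of additional uniform initial noise on u
#' @param bc boundary condition
#' @return a \linkS4class{SpaceTimeCube} of the voltage-like field
#' @export
fhnSimulate <- function(p = fhnParams(), cmap = NULL, offsets = NULL,
                        pathParams = NULL, T = 1000, dt = 0.01,
                        recordEvery = NULL, seed = NULL,
                        init = c("rest", "spiral", "pulse"), noiseAmp = 0,
                        bc = c("no_flux", "periodic")) {
    init <- match.arg(init)
    bc <- match.arg(bc)
    pathMode <- !is.null(offsets)
    if (pathMode && is.null(pathParams)) pathParams <- fhnPathParams()
    if (!pathMode && is.null(cmap))
        stop("supply cmap (static mode) or offsets (path mode)")
    if (!is.null(seed)) set.seed(seed)

    if (pathMode) {
        off <- propertyValues(offsets)
        c0mat <- fhnPathC(0, off, pathParams)
    } else {
        off <- matrix(0, nrow(propertyValues(cmap)), ncol(propertyValues(cmap)))
        c0mat <- propertyValues(cmap)
    }
    nx <- nrow(c0mat); ny <- ncol(c0mat)

    # per-site rest state for the initial c values
    u0 <- matrix(0, nx, ny); v0 <- matrix(0, nx, ny)
    uc <- unique(round(as.vector(c0mat), 10))
    lut <- vapply(uc, function(cc) fhnRestState(cc, p), numeric(2))
    idx <- match(round(as.vector(c0mat), 10), uc)
    u0[] <- lut[1, idx]; v0[] <- lut[2, idx]

    if (init == "spiral") {
        # open wavefront: an excited half-row backed by a refractory
        # band; the free end curls up into a rotating spiral
        r0 <- max(1, floor(nx / 2)); cs <- seq_len(floor(ny / 2))
        u0[r0:min(nx, r0 + 1), cs] <- u0[r0:min(nx, r0 + 1), cs] + 1.5
        rv <- min(nx, r0 + 2):min(nx, r0 + 5)
        v0[rv, cs] <- v0[rv, cs] + 0.3
    } else if (init == "pulse") {
        ci <- max(1, floor(nx / 2) - 1):min(nx, floor(nx / 2) + 1)
        cj <- max(1, floor(ny / 2) - 1):min(ny, floor(ny / 2) + 1)
        u0[ci, cj] <- u0[ci, cj] + 1
    }
    if (noiseAmp > 0)
        u0 <- u0 + matrix(stats::runif(nx * ny, -noiseAmp, noiseAmp), nx, ny)

    nSteps <- round(T / dt)
    if (is.null(recordEvery)) recordEvery <- max(1L, round(1 / dt))
    pathUpdate <- max(1L, round(0.5 / dt))  # path is slow (Tc >> dt)
    pp <- if (pathMode) pathParams else fhnPathParams()
    cube <- fhnSimCpp(u0, v0, c0mat, pathMode, off, pp$c0, pp$tc, pp$Tc,
                      p$a, p$b, p$gamma, p$eps, p$D, p$dx, dt,
                      as.integer(nSteps), as.integer(recordEvery),
                      as.integer(pathUpdate), .bcCode(bc))
    SpaceTimeCube(cube, dtRecord = dt * recordEvery, dx = p$dx,
                  modelName = if (pathMode) "fhn_path" else "fhn_static",
                  seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Static Gaussian excitability map with optional special sites
#'
#' Builds the static-variability inputs used across the FHN figure
#' set-ups: a base excitability \code{cBase} everywhere, an optional
#' fraction of sites at a lower-excitability value \code{cLow}, and an
#' optional central pacemaker site at \code{cPacemaker}.
#'
#' @param nx,ny lattice size
#' @param cBase base excitability value
#' @param cLow value assigned to a random fraction of sites (NULL for
#'   none)
#' @param lowFraction fraction of sites set to \code{cLow}
#' @param cPacemaker value of the central pacemaker site (NULL for none)
#' @param gaussianSd if positive, draw every site from
#'   \code{N(cBase, gaussianSd)} instead of the constant base
#' @param seed optional integer seed
#' @return a \linkS4class{CellPropertyMap} of kind
#'   \code{"excitability_c"}
#' @export
fhnExcitabilityMap <- function(nx, ny, cBase = 0.024, cLow = NULL,
                               lowFraction = 0, cPacemaker = NULL,
                               gaussianSd = 0, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    vals <- if (gaussianSd > 0)
        matrix(stats::rnorm(nx * ny, cBase, gaussianSd), nx, ny)
    else matrix(cBase, nx, ny)
    if (!is.null(cLow) && lowFraction > 0) {
        n <- round(lowFraction * nx * ny)
        vals[sample.int(nx * ny, n)] <- cLow
    }
    if (!is.null(cPacemaker))
        vals[floor(nx / 2), floor(ny / 2)] <- cPacemaker
    CellPropertyMap(vals, kind = "excitability_c")
}
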