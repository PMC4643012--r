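#' Schnakenberg reaction-diffusion parameters
#'
#' Kinetics of the two-species activator-depleted substrate system
#' \deqn{du/dt = \gamma(c_1 - c_{-1} u + c_3 u^2 v) + D_u \nabla^2 u}
#' \deqn{dv/dt = \gamma(c_2 - c_3 u^2 v) + D_v \nabla^2 v.}
#' The default constants produce spot patterns; \code{c2 = 1.57} produces
#' stripes.
#'
#' @param c1,cm1,c2,c3 kinetic constants (all > 0); \code{cm1} is the
#'   linear decay constant of \code{u}
#' @param gamma overall reaction scale factor
#' @param Du,Dv diffusion coefficients of activator and substrate
#' @return a parameter list of class \code{"SchnakenbergParams"}
#' @export
schnakenbergParams <- function(c1 = 0.05, cm1 = 1.0, c2 = 1.00, c3 = 1.0,
                               gamma = 2.0, Du = 1.0, Dv = 20.0) {
    stopifnot(c1 > 0, cm1 > 0, c2 > 0, c3 > 0, gamma > 0, Du > 0, Dv > 0)
    structure(list(c1 = c1, cm1 = cm1, c2 = c2, c3 = c3, gamma = gamma,
                   Du = Du, Dv = Dv), class = "SchnakenbergParams")
}

#' Homogeneous steady state of the Schnakenberg kinetics
#' @param p a \code{\link{schnakenbergParams}} list
#' @return named vector \code{c(u, v)}
#' @export
schnakenbergSteadyState <- function(p) {
    u <- (p$c1 + p$c2) / p$cm1
    v <- p$c2 / (p$c3 * u^2)
    c(u = u, v = v)
}

#' Schnakenberg reaction terms (diffusion excluded)
#'
#' @param u,v numeric matrices (the two concentration fields)
#' @param p a \code{\link{schnakenbergParams}} list
#' @return list with derivative matrices \code{du}, \code{dv}
#' @export
schnakenbergRHS <- function(u, v, p) {
    stopifnot(identical(dim(u), dim(v)))
    uv2 <- p$c3 * u^2 * v
    list(du = p$gamma * (p$c1 - p$cm1 * u + uv2),
         dv = p$gamma * (p$c2 - uv2))
}

#' Linear growth rate of a spatial mode (Turing dispersion relation)
#'
#' Largest real part of the eigenvalues of the reaction-diffusion
#' operator linearised about the homogeneous steady state, at spatial
#' wavenumber \code{k}.  A positive value at some \code{k > 0} together
#' with a negative value at \code{k = 0} signals a Turing instability.
#'
#' @param p a \code{\link{schnakenbergParams}} list
#' @param k wavenumber (scalar or vector, >= 0)
#' @return growth rate(s), same length as \code{k}
#' @export
turingDispersion <- function(p, k) {
    stopifnot(all(k >= 0))
    ss <- schnakenbergSteadyState(p)
    u <- ss["u"]; v <- ss["v"]
    fu <- p$gamma * (-p$cm1 + 2 * p$c3 * u * v)
    fv <- p$gamma * p$c3 * u^2
    gu <- -2 * p$gamma * p$c3 * u * v
    gv <- -p$gamma * p$c3 * u^2
    vapply(k, function(kk) {
        J <- matrix(c(fu - p$Du * kk^2, gu, fv, gv - p$Dv * kk^2), 2, 2)
        max(Re(eigen(J, only.values = TRUE)$values))
    }, numeric(1))
}

#' Simulate the Schnakenberg system on a lattice
#'
#' Forward-Euler integration with five-point diffusion.  The initial
#' state is the homogeneous steady state with independent uniform
#' perturbations in \code{[-initAmp, initAmp]} at every site.
#'
#' @param p a \code{\link{schnakenbergParams}} list
#' @param nx,ny lattice size
#' @param T total integration time
#' @param dt time step (default satisfies the diffusive stability bound
#'   for \code{Dv = 20})
#' @param recordEvery record every this many steps
#' @param seed integer seed for the initial perturbation
#' @param initAmp amplitude of the initial random perturbation
#' @param bc boundary condition
#' @return a \linkS4class{SpaceTimeCube} of the activator field \code{u}
#' @export
schnakenbergSimulate <- function(p = schnakenbergParams(), nx = 100, ny = 100,
                                 T = 500, dt = 0.01, recordEvery = NULL,
                                 seed = NULL, initAmp = 0.01,
                                 bc = c("no_flux", "periodic")) {
    bc <- match.arg(bc)
    nSteps <- round(T / dt)
    if (is.null(recordEvery)) recordEvery <- max(1L, nSteps %/% 50L)
    if (!is.null(seed)) set.seed(seed)
    ss <- schnakenbergSteadyState(p)
    u0 <- matrix(ss["u"] + runif(nx * ny, -initAmp, initAmp), nx, ny)
    v0 <- matrix(ss["v"] + runif(nx * ny, -initAmp, initAmp), nx, ny)
    cube <- schnakenbergSimCpp(u0, v0, p$c1, p$cm1, p$c2, p$c3, p$gamma,
                               p$Du, p$Dv, 1.0, dt, as.integer(nSteps),
                               as.integer(recordEvery), .bcCode(bc))
    SpaceTimeCube(cube, dtRecord = dt * recordEvery,
                  modelName = "schnakenberg",
                  seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Classify a converged Turing pattern as spots, stripes or none
#'
#' Operational morphological rule: the field is thresholded at its
#' median; connected components of the above-median set are measured
#' with \pkg{EBImage} moments.  Components that are numerous and round
#' (median eccentricity below \code{eccMax}, count at least
#' \code{minSpots}) are called spots; elongated components (median
#' length-to-width ratio above \code{elongMin}) are called stripes.  A
#' field whose relative amplitude is below \code{1e-3} is classified as
#' \code{"none"}.
#'
#' @param f numeric matrix (converged pattern snapshot)
#' @param eccMax eccentricity bound for spot components
#' @param minSpots minimum component count for the spot call
#' @param elongMin elongation (major axis / mean width) bound for the
#'   stripe call
#' @return one of \code{"spots"}, \code{"stripes"}, \code{"none"}
#' @export
classifyTuringPattern <- function(f, eccMax = 0.7, minSpots = 5,
                                  elongMin = 3) {
    .checkField(f)
    amp <- max(f) - min(f)
    if (amp < 1e-3 * max(1, abs(stats::median(f)))) return("none")
    mask <- f > stats::median(f)
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    mom <- EBImage::computeFeatures.moment(lab)
    shp <- EBImage::computeFeatures.shape(lab)
    if (is.null(mom) || nrow(mom) == 0) return("none")
    # drop fragments too small to have a meaningful shape
    keep <- shp[, "s.area"] >= 4
    if (!any(keep)) return("none")
    mom <- mom[keep, , drop = FALSE]
    shp <- shp[keep, , drop = FALSE]
    ecc <- mom[, "m.eccentricity"]
    major <- mom[, "m.majoraxis"]
    area <- shp[, "s.area"]
    elong <- major^2 / pmax(area, 1)   # length / mean-width proxy
    if (stats::median(elong) > elongMin) return("stripes")
    if (nrow(mom) >= minSpots && stats::median(ecc) < eccMax) return("spots")
    # fall back on the more extreme of the two diagnostics
    if (stats::median(ecc) >= eccMax) "stripes" else "spots"
}
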