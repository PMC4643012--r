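# shared fixtures and small utilities; everything is generated in code

# deterministic single-spiral movie spec around a random interior centre
spiralSpecAt <- function(seed, noiseSd = 0.05, shape = c(100, 100),
                         nFrames = 100) {
    set.seed(10000 + seed)
    ctr <- matrix(stats::runif(2, 25, shape[1] - 25), 1)
    chir <- sample(c(-1, 1), 1)
    syntheticSpec("archimedean_spiral", centers = ctr, periods = 20,
                  waveSpeeds = 0.7, chiralities = chir, noiseSd = noiseSd,
                  nFrames = nFrames, shape = shape, seed = seed)
}

# deterministic 1-3 source target movie spec with well-separated centres
targetSpecAt <- function(seed, noiseSd = 0.05, shape = c(100, 100),
                         nFrames = 120) {
    set.seed(20000 + seed)
    ns <- sample(1:3, 1)
    repeat {
        ctr <- cbind(stats::runif(ns, 15, shape[1] - 15),
                     stats::runif(ns, 15, shape[2] - 15))
        if (ns == 1 || min(stats::dist(ctr)) > 35) break
    }
    syntheticSpec("target", centers = ctr, periods = 20, waveSpeeds = 0.7,
                  t0 = 30, noiseSd = noiseSd, nFrames = nFrames,
                  shape = shape, seed = seed)
}

# sum of plaquette windings over a full (periodic) phase field: the net
# topological charge, computed by brute force
totalWindingPeriodic <- function(phi) {
    w <- function(x) atan2(sin(x), cos(x))
    nx <- nrow(phi); ny <- ncol(phi)
    s <- 0
    for (i in seq_len(nx)) {
        ip <- if (i == nx) 1L else i + 1L
        for (j in seq_len(ny)) {
            jp <- if (j == ny) 1L else j + 1L
            s <- s + w(phi[ip, j] - phi[i, j]) + w(phi[ip, jp] - phi[ip, j]) +
                 w(phi[i, jp] - phi[ip, jp]) + w(phi[i, j] - phi[i, jp])
        }
    }
    s / (2 * pi)
}

# bin sub-pixel events to the nearest site and accumulate counts
binEvents <- function(ev, shape) {
    m <- matrix(0, shape[1], shape[2])
    if (nrow(ev) == 0) return(m)
    i <- pmin(pmax(round(ev$x) + 1, 1), shape[1])
    j <- pmin(pmax(round(ev$y) + 1, 1), shape[2])
    for (r in seq_along(i)) m[i[r], j[r]] <- m[i[r], j[r]] + 1
    m
}
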