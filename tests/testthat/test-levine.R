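test_that("activation threshold has the exact limits and monotonicity", {
    p <- levineParams()
    # limits of the threshold expression
    expect_equal(levineThreshold(0, 0, p), p$cMax)
    expect_equal(levineThreshold(p$tRRP, 0, p), p$cMin)
    p1 <- levineParams(eMax = 1)
    expect_equal(levineThreshold(3, 1, p1), 0)
    expect_error(levineThreshold(-1, 0, p), "tau")
    expect_error(levineThreshold(0, 2, p1), "E")

    # strictly decreasing in tau and in E over a grid
    taus <- seq(0, p$tRRP, length.out = 30)
    thr <- levineThreshold(taus, 0, p)
    expect_true(all(diff(thr) < 0))
    Es <- seq(0, p$eMax, length.out = 20)
    thrE <- levineThreshold(p$tRRP / 2, Es, p)
    expect_true(all(diff(thrE) < 0))
})

test_that("cAMP field step decays, sources and conserves correctly", {
    p <- levineParams(Gamma = 0.3, rF = 2, D = 0.5, dt = 0.05)
    z <- matrix(0, 8, 8)
    expect_equal(campFieldStep(z, z, p), z)

    # homogeneous pure decay: c0 (1 - Gamma dt) after one step
    c0 <- matrix(1.5, 8, 8)
    expect_equal(campFieldStep(c0, z, p), c0 * (1 - p$Gamma * p$dt))

    # single firing site with Gamma = 0: total cAMP grows by rF dt per
    # step (the eight-point stencil conserves mass under no_flux)
    p0 <- levineParams(Gamma = 0, rF = 2, D = 0.5, dt = 0.05)
    s <- z; s[4, 4] <- 1
    cc <- z
    for (k in 1:20) {
        cc <- campFieldStep(cc, s, p0)
        expect_equal(sum(cc), k * p0$rF * p0$dt, tolerance = 1e-12)
    }
})

test_that("excitability grows monotonically and is capped at eMax", {
    p <- levineParams(eta = 0.01, beta = 0.2, dt = 0.1)
    E <- matrix(0.1, 6, 6)
    cc <- matrix(0.5, 6, 6)
    # eta = beta = 0 leaves E unchanged
    expect_equal(excitabilityStep(E, cc, levineParams(eta = 0, beta = 0)), E)
    # E at the cap stays at the cap
    Emax <- matrix(p$eMax, 6, 6)
    expect_equal(excitabilityStep(Emax, cc, p), Emax)
    # non-negative rates keep E non-decreasing at every site
    E2 <- excitabilityStep(E, cc, p)
    expect_true(all(E2 >= E))
})

test_that("the single-cell phase machine cycles correctly", {
    p <- levineParams(dt = 1, firingDuration = 1, tARP = 2, tRRP = 3,
                      cMax = 1, cMin = 0.1)
    cell <- list(phase = "ready", tau = 0, isPacemaker = FALSE, E = 0)

    # ready cell with supra-threshold cAMP fires
    f <- levineCellUpdate(cell, cLocal = 0.2, p)
    expect_equal(f$phase, "firing")

    # absolute refractoriness: never fires, whatever the cAMP level
    arp <- list(phase = "absolute_refractory", tau = 0, isPacemaker = FALSE,
                E = 0)
    expect_equal(levineCellUpdate(arp, cLocal = 100, p, uPM = 0)$phase,
                 "absolute_refractory")

    # pacemaker with pF = 1 fires from rest without any cAMP
    pm <- list(phase = "ready", tau = 0, isPacemaker = TRUE, E = 0)
    expect_equal(levineCellUpdate(pm, 0, levineParams(pF = 1), uPM = 0.5)$phase,
                 "firing")

    # full cycle: firing (1) -> ARP (2 steps) -> RRP (3 steps) -> ready
    phases <- character(0)
    st <- levineCellUpdate(cell, 0.2, p)            # fires at step 0
    for (k in 1:7) {
        st <- levineCellUpdate(st, 0, p, uPM = 1)
        phases <- c(phases, st$phase)
    }
    expect_equal(phases,
                 c("absolute_refractory", "absolute_refractory",
                   "relative_refractory", "relative_refractory",
                   "relative_refractory", "ready", "ready"))
})

test_that("quiescent lattice decays geometrically; no source stays silent", {
    # no pacemakers, eta = 0, E(0) = 0, c(0) = 0: identically zero
    pm <- CellPropertyMap(matrix(0, 12, 12), "pacemaker_mask")
    p <- levineParams(eta = 0)
    cube <- levineSimulate(pm, p, T = 10, seed = 1, E0 = 0)
    expect_equal(max(abs(frames(cube))), 0)

    # with Gamma > 0 and all cells quiescent, the total cAMP decays by
    # the factor (1 - Gamma dt) each step
    z <- matrix(0, 10, 10)
    cc <- matrix(runif(100), 10, 10)
    p2 <- levineParams(Gamma = 0.8, dt = 0.1)
    tot <- sum(cc)
    for (k in 1:50) {
        cc <- campFieldStep(cc, z, p2)
        tot <- tot * (1 - p2$Gamma * p2$dt)
        expect_equal(sum(cc), tot, tolerance = 1e-10)
    }
})

test_that("lattice runs are seed-reproducible", {
    pm <- pacemakerLayout(16, 16, kind = "random", fraction = 0.2, seed = 2)
    c1 <- levineSimulate(pm, T = 20, seed = 9, E0 = 0)
    c2 <- levineSimulate(pm, T = 20, seed = 9, E0 = 0)
    expect_identical(frames(c1), frames(c2))
})

test_that("pacemaker layouts have the advertised structure", {
    pmR <- pacemakerLayout(40, 40, "random", fraction = 0.2, seed = 1)
    frac <- mean(propertyValues(pmR) == 1)
    expect_gt(frac, 0.12); expect_lt(frac, 0.28)

    pmC <- pacemakerLayout(40, 40, "clustered", fraction = 0.2,
                           avenueWidth = 12, seed = 1)
    m <- propertyValues(pmC)
    avenue <- m[, 15:26]
    expect_equal(sum(avenue), 0)                   # central avenue is free
    expect_equal(sum(m == 1), round(0.2 * 1600))

    pm5 <- pacemakerLayout(40, 40, "fixed5", extraFraction = 0.01, seed = 1)
    expect_equal(sum(propertyValues(pm5) == 1), 5)
    expect_gt(sum(propertyValues(pm5) == 2), 0)
})
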