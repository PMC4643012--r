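test_that("deterministic CA follows the three update rules", {
    # all-susceptible grid has no excitation source
    g <- CAGrid(matrix(0L, 6, 6))
    expect_equal(caStates(caStep(g)), matrix(0L, 6, 6))

    # single interior E with r = 1: becomes R, 4-neighbours become E
    s <- matrix(0L, 5, 5); s[3, 3] <- 1L
    out <- caStates(caStep(CAGrid(s, r = 1L)))
    expect_equal(out[3, 3], 2L)
    expect_equal(out[2, 3], 1L); expect_equal(out[4, 3], 1L)
    expect_equal(out[3, 2], 1L); expect_equal(out[3, 4], 1L)
    expect_equal(sum(out == 1L), 4)

    # an E site is always R next step; R lasts exactly r steps; no site
    # skips the E -> R -> S sequence
    s2 <- matrix(0L, 6, 6); s2[3, 3] <- 1L
    g2 <- CAGrid(s2, r = 2L)
    g2a <- caStep(g2)
    expect_equal(caStates(g2a)[3, 3], 2L)
    g2b <- caStep(g2a)
    expect_equal(caStates(g2b)[3, 3], 2L)     # still refractory (r = 2)
    g2c <- caStep(g2b)
    expect_equal(caStates(g2c)[3, 3], 0L)     # recovered after r steps
})

test_that("open-wavefront construction and first step match hand execution", {
    g <- caOpenWavefrontInit(6, 6, 3, r = 1L)
    s <- caStates(g)
    expect_equal(sum(s == 1L), 3)
    expect_equal(sum(s == 2L), 3)
    row <- which(apply(s == 1L, 1, any))
    expect_true(all(s[row + 1L, s[row, ] == 1L] == 2L))

    # hand-derived next state for the 6x6 grid (front at row 3, cols 2:4)
    g0 <- CAGrid({m <- matrix(0L, 6, 6); m[3, 2:4] <- 1L; m[4, 2:4] <- 2L; m},
                 r = 1L)
    nxt <- caStates(caStep(g0))
    exp <- matrix(0L, 6, 6)
    exp[2, 2:4] <- 1L          # front advances one row
    exp[3, 1] <- 1L; exp[3, 5] <- 1L   # open ends add excited sites laterally
    exp[3, 2:4] <- 2L          # old front now refractory
    expect_equal(nxt, exp)

    expect_error(caOpenWavefrontInit(6, 6, 0), "positive")

    # full-width front construction: ny - 1 gives ny - 1 E and R sites
    g3 <- caOpenWavefrontInit(8, 8, 7)
    expect_equal(sum(caStates(g3) == 1L), 7)
    expect_equal(sum(caStates(g3) == 2L), 7)
})

test_that("open front self-sustains while a closed front annihilates", {
    # frozen regression of the deterministic spiral-genesis run
    g <- caOpenWavefrontInit(100, 100, 50, r = 1L)
    cube <- caSimulate(g, 600, recordEvery = 1L)
    ec <- caExcitedCounts(cube)
    expect_equal(ec[c(1, 2, 6, 51, 101, 301, 501, 601)],
                 c(50, 52, 80, 1900, 2500, 2500, 2500, 2500))
    expect_true(all(ec[101:601] > 0))
    f500 <- getFrame(cube, 501)
    expect_equal(sum(f500 == 1), 2500)
    expect_equal(sum(f500 == 2), 2500)
    expect_equal(rowSums(f500 == 1)[1:10],
                 c(24, 26, 26, 24, 24, 26, 26, 24, 24, 26))

    # replay determinism
    cube2 <- caSimulate(caOpenWavefrontInit(100, 100, 50, r = 1L), 600,
                        recordEvery = 1L)
    expect_identical(frames(cube), frames(cube2))

    # closed (full-width) front dies at the boundary
    gc <- caOpenWavefrontInit(100, 100, 100, r = 1L)
    ec2 <- caExcitedCounts(caSimulate(gc, 120, recordEvery = 1L))
    expect_equal(min(ec2), 0)
    expect_equal(which(ec2 == 0)[1] - 1L, 50L)
})

test_that("stochastic CA reduces to the deterministic rules at f=0, p=1", {
    set.seed(3)
    s <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    g <- CAGrid(s, r = 1L)
    expect_equal(caStates(caStepStochastic(g, f = 0, p = 1)),
                 caStates(caStep(g)))

    # f = 1 turns an all-S grid all-E in one step
    gS <- CAGrid(matrix(0L, 8, 8))
    expect_equal(caStates(caStepStochastic(gS, f = 1, p = 1)),
                 matrix(1L, 8, 8))
})

test_that("stochastic CA statistics match an independent re-implementation", {
    # brute-force second implementation of the same rules as oracle
    oracleStep <- function(m, f, p) {
        nx <- nrow(m); ny <- ncol(m)
        pad <- matrix(0L, nx + 2, ny + 2); pad[2:(nx + 1), 2:(ny + 1)] <- m
        excited <- (pad[1:nx, 2:(ny + 1)] == 1L) |
                   (pad[3:(nx + 2), 2:(ny + 1)] == 1L) |
                   (pad[2:(nx + 1), 1:ny] == 1L) |
                   (pad[2:(nx + 1), 3:(ny + 2)] == 1L)
        out <- m
        isS <- m == 0L; isE <- m == 1L; isR <- m == 2L
        u <- matrix(runif(nx * ny), nx, ny)
        out[isS] <- ifelse(excited[isS] | u[isS] < f, 1L, 0L)
        out[isE] <- 2L
        out[isR] <- ifelse(u[isR] < p, 0L, 2L)
        out
    }
    f <- 0.01; p <- 0.3; n <- 30; steps <- 1500
    set.seed(11)
    m <- matrix(0L, n, n)
    fracOracle <- numeric(steps)
    for (k in seq_len(steps)) { m <- oracleStep(m, f, p); fracOracle[k] <- mean(m == 1L) }
    g <- CAGrid(matrix(0L, n, n))
    set.seed(99)
    fracPkg <- numeric(steps)
    for (k in seq_len(steps)) { g <- caStepStochastic(g, f, p); fracPkg[k] <- mean(caStates(g) == 1L) }
    sel <- (steps / 2 + 1):steps
    # compare long-run means within 3 standard errors (block SE)
    blocks <- function(x) tapply(x, rep(seq_len(15), each = 50), mean)
    se <- sd(blocks(fracOracle[sel])) / sqrt(15)
    expect_lt(abs(mean(fracPkg[sel]) - mean(fracOracle[sel])),
              3 * max(se, 1e-4))
})

test_that("Schnakenberg reaction terms and steady state are exact", {
    p <- schnakenbergParams(c2 = 1.00)
    ss <- schnakenbergSteadyState(p)
    expect_equal(unname(ss["u"]), 1.05)
    expect_equal(unname(ss["v"]), 1.00 / 1.1025)
    u <- matrix(ss["u"], 5, 5); v <- matrix(ss["v"], 5, 5)
    d <- schnakenbergRHS(u, v, p)
    expect_lt(max(abs(d$du)), 1e-12)
    expect_lt(max(abs(d$dv)), 1e-12)

    # u = 0 gives du = gamma * c1 > 0
    d0 <- schnakenbergRHS(matrix(0, 4, 4), v[1:4, 1:4], p)
    expect_equal(d0$du, matrix(p$gamma * p$c1, 4, 4))

    # doubling gamma doubles both reaction terms
    p2 <- schnakenbergParams(gamma = 2 * p$gamma)
    set.seed(5)
    uu <- matrix(runif(16), 4, 4); vv <- matrix(runif(16), 4, 4)
    d1 <- schnakenbergRHS(uu, vv, p); d2 <- schnakenbergRHS(uu, vv, p2)
    expect_equal(d2$du, 2 * d1$du)
    expect_equal(d2$dv, 2 * d1$dv)
})

test_that("Turing dispersion relation identifies the instability band", {
    for (c2 in c(1.00, 1.57)) {
        p <- schnakenbergParams(c2 = c2)
        expect_lt(turingDispersion(p, 0), 0)      # homogeneous state stable
        ks <- seq(0.05, 2, by = 0.05)
        expect_gt(max(turingDispersion(p, ks)), 0)  # positive band at k > 0
    }
    # no Turing band with equal diffusion coefficients
    pe <- schnakenbergParams(Du = 1, Dv = 1)
    ks <- seq(0, 3, by = 0.05)
    g <- turingDispersion(pe, ks)
    expect_lte(max(g), g[1] + 1e-12)
})

test_that("homogeneous Schnakenberg state is preserved by the integrator", {
    cube <- schnakenbergSimulate(nx = 16, ny = 16, T = 5, dt = 0.01,
                                 seed = 1, initAmp = 0, recordEvery = 100)
    ss <- schnakenbergSteadyState(schnakenbergParams())
    dev <- apply(frames(cube), 3, function(f) max(abs(f - ss["u"])))
    expect_lt(max(dev), 1e-10)
})

test_that("pattern classifier recognises constructed ground truth", {
    # synthetic disk lattice -> spots
    X <- matrix(rep(1:48, 48), 48, 48)
    Y <- t(X)
    spots <- matrix(0, 48, 48)
    for (cx in seq(8, 44, by = 12)) for (cy in seq(8, 44, by = 12))
        spots <- spots + ((X - cx)^2 + (Y - cy)^2 < 9)
    expect_equal(classifyTuringPattern(spots + 0.01 * X / 48), "spots")

    # parallel bands -> stripes
    bands <- matrix(rep(as.numeric(sin(2 * pi * (1:48) / 12) > 0), 48),
                    48, 48, byrow = TRUE)
    expect_equal(classifyTuringPattern(bands + 0.01 * X / 48), "stripes")

    # homogeneous field -> none
    expect_equal(classifyTuringPattern(matrix(1, 32, 32)), "none")
})
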