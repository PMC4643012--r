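test_that("phase embedding recovers the phase of a pure sinusoid", {
    nx <- 12; ny <- 12; nt <- 80; period <- 16
    arr <- array(0, c(nx, ny, nt))
    for (t in seq_len(nt)) arr[, , t] <- cos(2 * pi * (t - 1) / period)
    cube <- SpaceTimeCube(arr)
    ph <- phaseEmbed(cube, delay = period / 4, window = period)
    k <- dim(ph)[3]
    x <- ph[6, 6, ]
    ok <- !is.na(x)
    # unwrapped phase advances by 2*pi per period
    dx <- diff(x[ok])
    dx <- atan2(sin(dx), cos(dx))
    expect_lt(max(abs(dx - 2 * pi / period)), 0.05)

    # constant movie: all site-frames masked
    cc <- SpaceTimeCube(array(2, c(8, 8, 30)))
    expect_true(all(is.na(phaseEmbed(cc, delay = 2, window = 8))))
})

test_that("phase of the negated movie is shifted by pi", {
    sp <- syntheticSpec("archimedean_spiral", centers = matrix(c(20, 20), 1),
                        periods = 20, waveSpeeds = 0.7, noiseSd = 0,
                        nFrames = 60, shape = c(40, 40), seed = 6)
    mv <- makeSpiralMovie(sp)
    a <- frames(mv$cube)
    phA <- phaseEmbed(SpaceTimeCube(a), delay = 5, window = 20)
    phB <- phaseEmbed(SpaceTimeCube(-a), delay = 5, window = 20)
    d <- phA - phB
    d <- atan2(sin(d), cos(d))
    ok <- !is.na(d)
    expect_lt(max(abs(abs(d[ok]) - pi)), 1e-6)
})

test_that("winding detector finds constructed singularities", {
    nx <- 21; ny <- 21
    X <- matrix(seq_len(nx) - 1, nx, ny)
    Y <- matrix(seq_len(ny) - 1, nx, ny, byrow = TRUE)
    phi <- atan2(Y - 10.5, X - 10.5)
    tips <- detectSpiralTips(phi, tFrame = 7)
    expect_equal(nrow(tips), 1)
    expect_lt(sqrt((tips$x - 10.5)^2 + (tips$y - 10.5)^2), 1.5)
    expect_equal(tips$chirality, "left")
    expect_equal(tips$t, 7)

    # -phi gives the same location with opposite chirality
    tips2 <- detectSpiralTips(-phi)
    expect_equal(tips2$x, tips$x)
    expect_equal(tips2$y, tips$y)
    expect_equal(tips2$chirality, "right")

    # a +1/-1 pair has total charge 0 on a periodic frame (brute-force
    # winding sum oracle)
    phi2 <- atan2(Y - 5.5, X - 5.5) - atan2(Y - 15.5, X - 15.5)
    pair <- detectSpiralTips(atan2(sin(phi2), cos(phi2)))
    expect_equal(sort(table(pair$chirality), decreasing = TRUE)[[1]],
                 sort(table(pair$chirality), decreasing = TRUE)[[2]])
    expect_lt(abs(totalWindingPeriodic(phi2)), 0.5)
})

test_that("target-origin detector matches constructed ground truth", {
    # single source: first origin within 2 sites, at the right time
    sp <- syntheticSpec("target", centers = matrix(c(30, 30), 1),
                        periods = 20, waveSpeeds = 0.7, t0 = 30,
                        noiseSd = 0, nFrames = 100, shape = c(70, 70),
                        seed = 1)
    mv <- makeTargetMovie(sp)
    org <- detectTargetOrigins(mv$cube)
    expect_equal(nrow(org), 1)
    expect_lt(sqrt((org$x - 30)^2 + (org$y - 30)^2), 2.1)
    expect_lt(abs(org$t - 30), 3.1)

    # all-quiet movie: empty result
    quiet <- SpaceTimeCube(array(0, c(20, 20, 40)))
    expect_equal(nrow(detectTargetOrigins(quiet, actThreshold = 0.5,
                                          windowW = 10)), 0)

    # two well-separated synchronized sources are both found
    sp2 <- syntheticSpec("target", centers = rbind(c(20, 20), c(60, 60)),
                        periods = 20, waveSpeeds = 0.7, t0 = 30,
                        noiseSd = 0, nFrames = 100, shape = c(80, 80),
                        seed = 2)
    mv2 <- makeTargetMovie(sp2)
    org2 <- detectTargetOrigins(mv2$cube)
    expect_equal(nrow(org2), 2)
    d1 <- min(sqrt((org2$x - 20)^2 + (org2$y - 20)^2))
    d2 <- min(sqrt((org2$x - 60)^2 + (org2$y - 60)^2))
    expect_lt(max(d1, d2), 2.1)
})

test_that("event plots are invariant under affine intensity rescaling", {
    sp <- spiralSpecAt(3, noiseSd = 0.03, shape = c(60, 60), nFrames = 80)
    mv <- makeSpiralMovie(sp)
    ep1 <- buildEventPlot(mv$cube)
    scaled <- SpaceTimeCube(7.3 * frames(mv$cube) - 11)
    ep2 <- buildEventPlot(scaled)
    expect_equal(events(ep1), events(ep2))
})

test_that("top-down view collapses events onto the lattice", {
    ev <- data.frame(kind = c("spiral_tip", "spiral_tip", "target_origin"),
                     chirality = c("left", "right", "none"),
                     x = c(3.4, 2.6, 7), y = c(2.4, 1.6, 8), t = c(1, 5, 2))
    ep <- EventPlot(ev, shape = c(12, 12), nFrames = 10)
    tips <- topDownView(ep, "spiral_tip")
    expect_equal(tips[4, 3], 2)            # both tips bin to site (4, 3)
    expect_equal(sum(tips), 2)
    org <- topDownView(ep, "target_origin")
    expect_equal(org[8, 9], 1)
    expect_equal(sum(org), 1)

    # empty plot gives the zero field
    ep0 <- EventPlot(emptyEvents(), shape = c(5, 5), nFrames = 3)
    expect_equal(topDownView(ep0, "spiral_tip"), matrix(0, 5, 5))
})

test_that("an eventless movie yields an empty event plot", {
    quiet <- SpaceTimeCube(array(1, c(16, 16, 30)))
    ep <- buildEventPlot(quiet)
    expect_equal(nrow(events(ep)), 0)
    expect_equal(nFrames(ep), 30)
})
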