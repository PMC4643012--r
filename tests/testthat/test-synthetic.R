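test_that("synthetic movie generation is deterministic and validated", {
    sp <- syntheticSpec("archimedean_spiral", centers = matrix(c(30, 30), 1),
                        periods = 20, waveSpeeds = 0.7, noiseSd = 0.05,
                        nFrames = 40, shape = c(60, 60), seed = 5)
    m1 <- makeSpiralMovie(sp)
    m2 <- makeSpiralMovie(sp)
    expect_identical(frames(m1$cube), frames(m2$cube))
    expect_equal(nrow(events(m1$truth)), 40)   # tip listed in every frame
    expect_true(all(events(m1$truth)$kind == "spiral_tip"))

    expect_error(syntheticSpec("target", centers = rbind(c(10, 10), c(12, 10))),
                 "closer than 5 sites")
})

test_that("target ground truth lists one origin per source", {
    ctr <- rbind(c(20, 20), c(50, 55), c(20, 55))
    sp <- syntheticSpec("target", centers = ctr, periods = 20,
                        waveSpeeds = 0.7, t0 = c(25, 30, 35), noiseSd = 0,
                        nFrames = 80, shape = c(75, 75), seed = 2)
    mv <- makeTargetMovie(sp)
    tr <- events(mv$truth)
    expect_equal(nrow(tr), 3)
    expect_setequal(tr$t, c(25, 30, 35))
    expect_true(all(tr$chirality == "none"))
})

test_that("single spiral is recovered within 2 sites with correct handedness", {
    for (chir in c(1, -1)) {
        sp <- syntheticSpec("archimedean_spiral",
                            centers = matrix(c(45, 55), 1), periods = 20,
                            waveSpeeds = 0.7, chiralities = chir,
                            noiseSd = 0, nFrames = 90, shape = c(100, 100),
                            seed = 3)
        mv <- makeSpiralMovie(sp)
        ep <- buildEventPlot(mv$cube)
        m <- matchEvents(ep, mv$truth, "spiral_tip", radius = 2)
        expect_gte(m$precision, 0.9)
        expect_gte(m$recall, 0.9)
        expect_lte(m$locError, 2)
        expect_equal(m$chiralityAcc, 1)
    }
})

test_that("two opposite spirals carry zero net topological charge", {
    # winding-sum oracle on the analytic phase field of the composite
    nx <- 60
    X <- matrix(seq_len(nx) - 1, nx, nx)
    Y <- matrix(seq_len(nx) - 1, nx, nx, byrow = TRUE)
    phi <- atan2(Y - 20, X - 20) - atan2(Y - 40, X - 40)
    expect_lt(abs(totalWindingPeriodic(phi)), 0.5)

    sp <- syntheticSpec("archimedean_spiral",
                        centers = rbind(c(25, 25), c(75, 75)),
                        periods = 20, waveSpeeds = 0.7,
                        chiralities = c(1, -1), noiseSd = 0,
                        nFrames = 90, shape = c(100, 100), seed = 4)
    mv <- makeSpiralMovie(sp)
    ep <- buildEventPlot(mv$cube)
    tips <- events(ep)[events(ep)$kind == "spiral_tip", ]
    # both handedness classes present near their centres
    d1 <- sqrt((tips$x - 25)^2 + (tips$y - 25)^2)
    d2 <- sqrt((tips$x - 75)^2 + (tips$y - 75)^2)
    expect_true(any(d1 < 3 & tips$chirality == "left"))
    expect_true(any(d2 < 3 & tips$chirality == "right"))
})

test_that("detector meets precision and recall on the noisy suite", {
    # 3 spiral + 3 target movies at 5% noise (the full 20-movie suite is
    # exercised by the acceptance checks)
    for (k in 1:3) {
        mv <- makeSpiralMovie(spiralSpecAt(k))
        ep <- buildEventPlot(mv$cube)
        m <- matchEvents(ep, mv$truth, "spiral_tip", radius = 3)
        expect_gte(m$precision, 0.9)
        expect_gte(m$recall, 0.9)
        expect_equal(m$chiralityAcc, 1)
        expect_equal(sum(events(ep)$kind == "target_origin"), 0)
    }
    for (k in 1:3) {
        mv <- makeTargetMovie(targetSpecAt(k))
        ep <- buildEventPlot(mv$cube)
        m <- matchEvents(ep, mv$truth, "target_origin", radius = 3,
                         window = 20)
        expect_gte(m$precision, 0.9)
        expect_gte(m$recall, 0.9)
        expect_equal(sum(events(ep)$kind == "spiral_tip"), 0)
    }
})
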