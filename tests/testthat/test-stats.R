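test_that("occupancy maps count, sum and add correctly", {
    ep1 <- EventPlot(data.frame(kind = "spiral_tip", chirality = "left",
                                x = c(2, 2, 7), y = c(3, 3, 1),
                                t = c(1, 4, 2)),
                     shape = c(10, 10), nFrames = 10)
    ep0 <- EventPlot(emptyEvents(), shape = c(10, 10), nFrames = 10)

    occ0 <- occupancyMap(list(ep0), "spiral_tip")
    expect_equal(sum(counts(occ0)), 0)

    occ1 <- occupancyMap(list(ep1), "spiral_tip")
    expect_equal(sum(counts(occ1)), 3)
    expect_equal(counts(occ1)[3, 4], 2)

    # concatenating run lists sums the maps
    occ2 <- occupancyMap(list(ep1, ep1, ep0), "spiral_tip")
    expect_equal(counts(occ2), 2 * counts(occ1))
    expect_equal(nRuns(occ2), 3L)

    epBad <- EventPlot(emptyEvents(), shape = c(8, 8), nFrames = 10)
    expect_error(occupancyMap(list(ep1, epBad)), "shape")
})

test_that("Gaussian smoothing is exact in its limiting cases", {
    m <- matrix(runif(400), 20, 20)
    expect_identical(gaussianSmooth(m, 0), m)
    expect_error(gaussianSmooth(m, -1), "non-negative")

    cst <- matrix(4.2, 15, 15)
    expect_equal(gaussianSmooth(cst, 3), cst, tolerance = 1e-12)

    # interior unit impulse, radius 2: centre value ~ 1/(2 pi 2^2)
    imp <- matrix(0, 41, 41); imp[21, 21] <- 1
    sm <- gaussianSmooth(imp, 2)
    expect_equal(sm[21, 21], 1 / (2 * pi * 4), tolerance = 0.05)

    # total mass is preserved under the reflecting boundary
    set.seed(12)
    for (r in c(1, 4, 16)) {
        x <- matrix(rexp(30 * 24), 30, 24)
        expect_lt(abs(sum(gaussianSmooth(x, r)) - sum(x)), 1e-8)
    }
})

test_that("Spearman correlation behaves at its extremes and null", {
    set.seed(3)
    a <- matrix(rnorm(100), 10, 10)
    expect_equal(spearmanMap(a, a), 1)
    # a strictly decreasing transform reverses the ranks
    expect_equal(spearmanMap(a, -a), -1)
    expect_error(spearmanMap(matrix(1, 5, 5), a[1:5, 1:5]), "constant")

    # invariance under strictly monotone transforms of either map
    b <- matrix(rnorm(100), 10, 10)
    r0 <- spearmanMap(a, b)
    expect_equal(spearmanMap(exp(a), b), r0)
    expect_equal(spearmanMap(a, b^3 + 5 * b), r0)

    # null distribution at n = 10^4 sites: |rho| < 0.03 in ~99% of seeds
    hits <- 0
    nrep <- 200
    for (k in seq_len(nrep)) {
        u <- matrix(runif(1e4), 100, 100)
        v <- matrix(runif(1e4), 100, 100)
        if (abs(spearmanMap(u, v)) < 0.03) hits <- hits + 1
    }
    expect_gte(hits / nrep, 0.96)
})

test_that("correlation curves have the right structure", {
    ep <- EventPlot(data.frame(kind = c("spiral_tip", "target_origin"),
                               chirality = c("left", "none"),
                               x = c(5, 20), y = c(5, 20), t = c(3, 1)),
                    shape = c(30, 30), nFrames = 20)
    prop <- CellPropertyMap(matrix(rexp(900), 30, 30), "time_offset")
    radii <- c(1, 2, 4)
    cv <- correlationVsRadius(list(ep, ep, ep), prop, radii = radii)
    expect_equal(nrow(cv), 3 * length(radii))
    # identical runs: SEM exactly zero wherever defined
    expect_true(all(cv$sem_rho[cv$n_used > 1] == 0))
    expect_setequal(unique(cv$radius), radii)
})

test_that("Voronoi edge geometry and permutation test are calibrated", {
    seeds <- rbind(c(10, 10), c(30, 10), c(20, 30))
    shape <- c(40, 40)
    edges <- voronoiEdgePoints(seeds, shape, step = 0.25)
    # every edge sample is (nearly) equidistant from its two nearest seeds
    d <- apply(edges, 1, function(pt) {
        dd <- sort(sqrt((seeds[, 1] - pt[1])^2 + (seeds[, 2] - pt[2])^2))
        dd[2] - dd[1]
    })
    expect_lt(max(d), 0.05)
    expect_error(voronoiEdgePoints(seeds[1:2, ], shape), "3 seeds")
    coll <- rbind(c(1, 1), c(2, 2), c(3, 3))
    expect_error(voronoiEdgePoints(coll, shape), "non-collinear")

    # tips placed exactly on edge points: zero distance, minimal p
    tipIdx <- seq(1, nrow(edges), length.out = 12)
    tips <- edges[round(tipIdx), , drop = FALSE]
    st <- voronoiEdgeStat(tips, seeds, shape, nPerm = 99, seed = 1)
    expect_lt(st$mean_distance, 1e-9)
    expect_equal(st$p_value, 1 / 100)

    # tips at the seeds themselves sit strictly inside their cells
    st2 <- voronoiEdgeStat(seeds, seeds, shape, nPerm = 49, seed = 2)
    expect_gt(st2$mean_distance, 1)

    # uniform random tips: p roughly uniform (mean near 1/2)
    set.seed(5)
    ps <- replicate(30, {
        tt <- cbind(runif(15, 0, 39), runif(15, 0, 39))
        voronoiEdgeStat(tt, seeds, shape, nPerm = 39)$p_value
    })
    expect_gt(mean(ps), 0.25)
    expect_lt(mean(ps), 0.75)
})
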