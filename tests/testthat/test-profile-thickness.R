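# Profile extraction and bilayer feature detection.

test_that("profiles reproduce raw voxel values along a grid axis", {
    set.seed(21)
    v <- DensityVolume(array(rnorm(16^3), c(16, 16, 16)), voxelSize = 1)
    # voxel-centre-aligned start, direction +x
    pt <- c(8.5, 4.5, 6.5)    # centre of voxel (8, 4, 6), 0-based
    pr <- extractProfile(v, pt, c(1, 0, 0), halfLength = 3)
    expect_equal(pr$samples, voxelData(v)[6:12, 5, 7], tolerance = 1e-12)
    const <- DensityVolume(array(2, c(12, 12, 12)))
    prc <- extractProfile(const, c(6, 6, 6), c(1, 1, 1) / sqrt(3), 2)
    expect_equal(prc$samples, rep(2, length(prc$samples)),
                 tolerance = 1e-12)
    expect_error(extractProfile(v, c(1, 8, 8), c(1, 0, 0), 10),
                 "exits the volume")
})

test_that("leaflet minima and inflections match the analytic profile", {
    # fine sampling: minima at the numerically minimized trough centres,
    # outer inflections at the maximum-gradient points near +-(t/2 + sigma)
    for (t in c(4, 5, 6, 7)) {
        pr <- analyticBilayerProfile(t, 1, spacing = 0.2, halfLength = 12)
        ft <- detectBilayerFeatures(pr, inflectionSide = "outer")
        oracle <- diff(bilayerMinimaOracle(t, 1))
        expect_equal(ft$thicknessMinima, oracle, tolerance = 0.1,
                     info = paste("t =", t))
        expect_equal(ft$thicknessInflection, t + 2, tolerance = 0.15,
                     info = paste("t =", t))
        expect_equal(ft$centerMaxPosition, 0, tolerance = 0.1)
        inner <- detectBilayerFeatures(pr, inflectionSide = "inner")
        # outer >= minima >= inner ordering on noiseless profiles
        expect_gte(ft$thicknessInflection, ft$thicknessMinima)
        expect_gte(ft$thicknessMinima, inner$thicknessInflection)
    }
})

test_that("minima-based thickness is unbiased at tomographic sampling", {
    # t in 4..7 nm at 0.87 nm voxels: bias below half a voxel
    for (t in c(4, 5, 6, 7)) {
        pr <- analyticBilayerProfile(t, 1, spacing = 0.87,
                                     halfLength = 12)
        ft <- detectBilayerFeatures(pr)
        expect_lt(abs(ft$thicknessMinima - diff(bilayerMinimaOracle(t, 1))),
                  0.87 / 2)
    }
})

test_that("degenerate profiles are rejected with clear errors", {
    x <- seq(-8, 8, by = 0.5)
    single <- structure(list(samples = -exp(-x^2 / 2), positions = x,
                             spacing = 0.5, axisOrigin = c(0, 0, 0),
                             axisDirection = c(0, 0, 1)),
                        class = "IntensityProfile")
    expect_error(detectBilayerFeatures(single), "no bilayer")
    short <- structure(list(samples = rnorm(5), positions = 1:5,
                            spacing = 1, axisOrigin = c(0, 0, 0),
                            axisDirection = c(0, 0, 1)),
                       class = "IntensityProfile")
    expect_error(detectBilayerFeatures(short), "too short")
    # prominence gate: shallow noise dips are not leaflets
    pr <- analyticBilayerProfile(6, 1, 0.3, 12)
    pr$samples <- pr$samples + 0.02 * sin(pr$positions * 9)
    ft <- detectBilayerFeatures(pr, minProminence = 0.1)
    expect_equal(ft$thicknessMinima, 6, tolerance = 0.3)
})

test_that("grouped thickness measurement recovers a thinned patch", {
    sc <- makeBilayerScene(bilayerSpec(gridShape = c(48, 48, 40),
                                       thickness = 6, troughWidth = 1,
                                       patchRadius = 12,
                                       patchThinning = 0.6,
                                       noiseSd = 0.02, seed = 5))
    vs <- 0.87
    ctr <- c(24, 24) * vs
    set.seed(31)
    ang <- runif(40, 0, 2 * pi)
    rad <- c(runif(20, 0, 8), runif(20, 15, 19))
    sites <- data.frame(x = ctr[1] + rad * cos(ang),
                        y = ctr[2] + rad * sin(ang),
                        z = 20 * vs, dx = 0, dy = 0, dz = 1,
                        group = rep(c("internal", "external"), each = 20))
    # native voxel sampling: trilinear volumes are piecewise linear, so
    # finer-than-voxel sampling quantizes minima to grid knots, while
    # voxel-spaced samples + parabolic refinement localize sub-voxel
    gm <- measureGroupThickness(sc$volume, sites, halfLength = 10,
                                basis = "minima")
    res <- groupCompare(gm)
    expect_equal(unname(res$medians["external"] - res$medians["internal"]),
                 0.6, tolerance = 0.2)
    expect_lt(res$test$p_value, 0.05)
})

test_that("identical groups on a uniform bilayer are indistinguishable", {
    sc <- makeBilayerScene(bilayerSpec(gridShape = c(48, 48, 40),
                                       thickness = 6, troughWidth = 1,
                                       noiseSd = 0.01, seed = 2))
    vs <- 0.87
    set.seed(8)
    sites <- data.frame(x = runif(20, 8, 33), y = runif(20, 8, 33),
                        z = 20 * vs, dx = 0, dy = 0, dz = 1,
                        group = rep(c("g1", "g2"), 10))
    gm <- measureGroupThickness(sc$volume, sites, halfLength = 10,
                                basis = "minima")
    res <- groupCompare(gm)
    expect_lt(abs(diff(unname(res$medians))), 0.05)
})

test_that("sites in empty space fail as a group", {
    sc <- makeBilayerScene(bilayerSpec(gridShape = c(48, 48, 40)))
    sites <- data.frame(x = c(10, 12), y = c(10, 12), z = 2 * 0.87,
                        dx = 1, dy = 0, dz = 0, group = "void")
    expect_error(measureGroupThickness(sc$volume, sites, halfLength = 5,
                                       minProminence = 0.05),
                 "no successful measurements")
})

test_that("thickness is equivariant under scene rotation", {
    sc <- makeBilayerScene(bilayerSpec(gridShape = c(40, 40, 40),
                                       thickness = 6, troughWidth = 1))
    vs <- 0.87
    ctr <- c(20, 20, 20) * vs
    base <- detectBilayerFeatures(extractProfile(sc$volume, ctr,
                                                 c(0, 0, 1), 10))
    # tilted extraction direction through the same point: the membrane
    # plane is z = const, so thickness along a tilted axis grows as
    # 1/cos(angle); compare after projection
    dir <- c(sin(0.3), 0, cos(0.3))
    tilt <- detectBilayerFeatures(extractProfile(sc$volume, ctr, dir, 10))
    expect_equal(tilt$thicknessMinima * cos(0.3), base$thicknessMinima,
                 tolerance = 0.25)
})
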