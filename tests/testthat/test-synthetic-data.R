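# Seeded synthetic-scene generators: bilayer volumes, oracle meshes,
# pose populations, toy subtomograms.

test_that("bilayer trough positions match the closed-form oracle", {
    spec <- bilayerSpec(gridShape = c(32, 32, 48), voxelSize = 0.5,
                        thickness = 6, troughWidth = 1)
    sc <- makeBilayerScene(spec)
    oracle <- bilayerMinimaOracle(6, 1)
    expect_equal(diff(oracle), 6, tolerance = 1e-3)   # wide separation
    ctr <- dim(voxelData(sc$volume)) * 0.5 / 2
    pr <- extractProfile(sc$volume, ctr, c(0, 0, 1), halfLength = 10)
    ft <- detectBilayerFeatures(pr)
    expect_equal(ft$thicknessMinima, diff(oracle),
                 tolerance = 0.25)                    # half a voxel
})

test_that("bilayer ground truth reflects the thinned patch", {
    sc <- makeBilayerScene(bilayerSpec(patchRadius = 15,
                                       patchThinning = 1, thickness = 6))
    expect_equal(unique(sc$truth$thickness[sc$truth$inPatch]), 5)
    expect_equal(unique(sc$truth$thickness[!sc$truth$inPatch]), 6)
    # mask envelope covers the leaflets
    m <- voxelData(sc$mask)
    expect_true(all(m >= 0 & m <= 1))
    expect_gt(sum(m > 0.5), 0)
})

test_that("bilayer generator is seed-deterministic, noise-only varies", {
    a <- makeBilayerScene(bilayerSpec(seed = 1))
    b <- makeBilayerScene(bilayerSpec(seed = 2))
    expect_identical(voxelData(a$volume), voxelData(b$volume))
    a2 <- makeBilayerScene(bilayerSpec(seed = 1, noiseSd = 0.1))
    a3 <- makeBilayerScene(bilayerSpec(seed = 1, noiseSd = 0.1))
    b2 <- makeBilayerScene(bilayerSpec(seed = 2, noiseSd = 0.1))
    expect_identical(voxelData(a2$volume), voxelData(a3$volume))
    expect_false(identical(voxelData(a2$volume), voxelData(b2$volume)))
    # the noiseless parts agree; only the noise fields differ
    expect_equal(sd(voxelData(a2$volume) - voxelData(b2$volume)),
                 sqrt(2) * 0.1, tolerance = 0.05)
})

test_that("bilayer generator rejects impossible geometry", {
    expect_error(makeBilayerScene(bilayerSpec(gridShape = c(16, 16, 48),
                                              patchRadius = 15,
                                              patchThinning = 1)),
                 "too small")
    expect_error(makeBilayerScene(bilayerSpec(gridShape = c(64, 64, 10))),
                 "too small")
    expect_error(bilayerSpec(thickness = -1), "thickness")
    expect_error(bilayerSpec(patchThinning = 7, thickness = 6), "smaller")
})

test_that("parametric meshes carry exact analytic curvature", {
    sph <- makeParametricMesh(meshSpec("sphere", radius = 10,
                                       targetVertexCount = 642))
    expect_true(all(abs(sph$H - 0.1) < 1e-12))
    expect_true(all(abs(sph$K - 0.01) < 1e-12))
    expect_equal(sqrt(rowSums(vertices(sph$mesh)^2)),
                 rep(10, nrow(vertices(sph$mesh))))
    pl <- makeParametricMesh(meshSpec("plane", extent = 20,
                                      targetVertexCount = 400))
    expect_true(all(pl$H == 0) && all(pl$K == 0))
    cyl <- makeParametricMesh(meshSpec("cylinder", radius = 5,
                                       extent = 20,
                                       targetVertexCount = 500))
    expect_true(all(abs(cyl$k1 - 0.2) < 1e-12))
    expect_true(all(cyl$k2 == 0) && all(cyl$K == 0))
    sad <- makeParametricMesh(meshSpec("saddle", radius = 10, extent = 20,
                                       targetVertexCount = 400))
    expect_true(all(sad$K < 0))
    expect_error(meshSpec("torus"), "arg")
})

test_that("jittered oracle meshes stay on the analytic surface", {
    sph <- makeParametricMesh(meshSpec("sphere", radius = 10,
                                       targetVertexCount = 642,
                                       jitterSd = 0.05, seed = 3))
    expect_equal(sqrt(rowSums(vertices(sph$mesh)^2)),
                 rep(10, nrow(vertices(sph$mesh))))
    base <- makeParametricMesh(meshSpec("sphere", radius = 10,
                                        targetVertexCount = 642))
    expect_false(identical(vertices(sph$mesh), vertices(base$mesh)))
})

test_that("pose population realizes the requested encapsulation truth", {
    pop <- makePosePopulation(populationSpec(nVaultsCytosolic = 50,
                                             encapsulationFraction = 0.1,
                                             seed = 7))
    expect_equal(sum(pop$truth$encapsulated), 5)   # floor(0.1 * 50)
    enc <- which(pop$truth$encapsulated)
    d <- sqrt(rowSums((positions(pop$ribosomes)[enc, , drop = FALSE] -
                       positions(pop$vaults)[pop$truth$vaultIndex[enc], ,
                                             drop = FALSE])^2))
    expect_true(all(d < 10))                       # inside the pairing rule
    free <- which(!pop$truth$encapsulated)
    vp <- positions(pop$vaults)
    dfree <- vapply(free, function(i)
        min(sqrt(colSums((t(vp) - positions(pop$ribosomes)[i, ])^2))),
        numeric(1))
    expect_true(all(dfree >= 20))                  # two cutoffs away
    pop2 <- makePosePopulation(populationSpec(nVaultsCytosolic = 50,
                                              encapsulationFraction = 0.1,
                                              seed = 7))
    expect_identical(positions(pop2$ribosomes), positions(pop$ribosomes))
})

test_that("concentrated orientations approach the target axis as kappa grows", {
    spec <- populationSpec(nVaultsCytosolic = 40,
                           encapsulationFraction = 1, kappa = 1e6,
                           nFreeRibosomes = 0, seed = 2)
    pop <- makePosePopulation(spec)
    expect_true(all(pop$truth$relativeAngle < 1))   # within one degree
})

test_that("uniform relative orientations have near-zero resultant", {
    set.seed(9)
    rot <- randomRotations(10000)
    ax <- t(apply(rot, 3, function(R) R %*% c(0, 0, 1)))
    expect_lt(sqrt(sum(colMeans(ax)^2)), 0.05)
})

test_that("pose population packing fails loudly in a too-small box", {
    expect_error(makePosePopulation(populationSpec(nVaultsCytosolic = 100,
                                                   boxExtent = 60,
                                                   minSeparation = 40,
                                                   seed = 1)),
                 "packing")
})

test_that("noiseless subtomograms equal the rotated template", {
    tp <- makeToyTemplates(16)
    R <- axisAngleMatrix(c(0, 0, 1), 35)
    st <- makeSubtomograms(tp$templateA, tp$templateB, 1, noiseSd = 0,
                           classes = "A",
                           rotations = array(R, c(3, 3, 1)))
    direct <- rotateVolume(tp$templateA, R)
    expect_equal(voxelData(st$volumes[[1]]), voxelData(direct))
    # a 90-degree wedge removes nothing
    stw <- makeSubtomograms(tp$templateA, tp$templateB, 1, noiseSd = 0,
                            wedgeHalfangle = 90, classes = "A",
                            rotations = array(R, c(3, 3, 1)))
    expect_equal(voxelData(stw$volumes[[1]]), voxelData(direct),
                 tolerance = 1e-12)
    # a real wedge does remove signal
    stw2 <- makeSubtomograms(tp$templateA, tp$templateB, 1, noiseSd = 0,
                             wedgeHalfangle = 60, classes = "A",
                             rotations = array(R, c(3, 3, 1)))
    expect_gt(max(abs(voxelData(stw2$volumes[[1]]) - voxelData(direct))),
              1e-3)
    small <- DensityVolume(array(0, c(8, 8, 8)))
    expect_error(makeSubtomograms(tp$templateA, small, 1), "same shape")
})

test_that("identity rotation leaves a volume bit-identical", {
    tp <- makeToyTemplates(12)
    expect_equal(voxelData(rotateVolume(tp$templateA, diag(3))),
                 voxelData(tp$templateA), tolerance = 1e-12)
})
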