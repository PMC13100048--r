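# Ribosome-vault pairing, relative orientations, spherical histograms
# and contingency summaries.

test_that("pairing honours the inclusive distance cutoff", {
    vaults <- PoseSet(rbind(c(0, 0, 0), c(100, 0, 0)),
                      randomRotations(2, seed = 1))
    ribos <- PoseSet(rbind(c(9.9, 0, 0), c(100, 10.1, 0), c(50, 50, 50)),
                     randomRotations(3, seed = 2))
    pr <- pairNearest(ribos, vaults, cutoff = 10)
    expect_equal(pr$ribosomeIndex, 1L)
    expect_equal(pr$vaultIndex, 1L)
    expect_equal(pr$distance, 9.9)
    # exact boundary is included
    prb <- pairNearest(PoseSet(rbind(c(10, 0, 0)),
                               randomRotations(1, seed = 3)),
                       vaults, cutoff = 10)
    expect_equal(nrow(prb), 1L)
})

test_that("equidistant vaults break ties toward the lower index", {
    vaults <- PoseSet(rbind(c(-5, 0, 0), c(5, 0, 0)),
                      randomRotations(2, seed = 4))
    ribo <- PoseSet(rbind(c(0, 0, 0)), randomRotations(1, seed = 5))
    expect_equal(pairNearest(ribo, vaults, cutoff = 10)$vaultIndex, 1L)
})

test_that("pairing is restricted to matching tomograms", {
    vaults <- PoseSet(rbind(c(0, 0, 0)), randomRotations(1, seed = 1),
                      tomogramId = "t1")
    ribos <- PoseSet(rbind(c(1, 0, 0)), randomRotations(1, seed = 2),
                     tomogramId = "t2")
    expect_equal(nrow(pairNearest(ribos, vaults)), 0L)
})

test_that("generator encapsulations are recovered exactly", {
    pop <- makePosePopulation(populationSpec(nVaultsCytosolic = 50,
                                             encapsulationFraction = 0.1,
                                             seed = 7))
    pr <- pairNearest(pop$ribosomes, pop$vaults, cutoff = 10)
    truthIdx <- which(pop$truth$encapsulated)
    expect_setequal(pr$ribosomeIndex, truthIdx)
    expect_equal(pr$vaultIndex,
                 pop$truth$vaultIndex[pr$ribosomeIndex])
})

test_that("relative axes equal the direct matrix product and are
           invariant to global rotation", {
    set.seed(6)
    vaults <- PoseSet(matrix(runif(9, 0, 50), 3), randomRotations(3))
    ribos <- PoseSet(positions(vaults) + 2, randomRotations(3))
    pr <- pairNearest(ribos, vaults, cutoff = 5)
    ref <- c(0, 0, 1)
    ax <- relativeAxis(pr, ref)
    for (k in seq_len(nrow(pr))) {
        Rv <- rotations(vaults)[, , pr$vaultIndex[k]]
        Rr <- rotations(ribos)[, , pr$ribosomeIndex[k]]
        expect_equal(ax[k, ], drop(t(Rv) %*% Rr %*% ref),
                     tolerance = 1e-12)
    }
    G <- randomRotations(1, seed = 8)[, , 1]
    rotSet <- function(ps) {
        rot <- rotations(ps)
        for (i in seq_len(length(ps))) rot[, , i] <- G %*% rot[, , i]
        PoseSet(positions(ps) %*% t(G), rot)
    }
    pr2 <- pairNearest(rotSet(ribos), rotSet(vaults), cutoff = 5)
    expect_equal(pr2$distance, pr$distance, tolerance = 1e-9)
    expect_equal(relativeAxis(pr2, ref), ax, tolerance = 1e-9)
})

test_that("identical poses give the reference axis itself", {
    R <- randomRotations(1, seed = 9)[, , 1]
    vaults <- PoseSet(rbind(c(0, 0, 0)), array(R, c(3, 3, 1)))
    ribos <- PoseSet(rbind(c(1, 0, 0)), array(R, c(3, 3, 1)))
    pr <- pairNearest(ribos, vaults)
    expect_equal(drop(relativeAxis(pr, c(0, 0, 1))), c(0, 0, 1),
                 tolerance = 1e-12)
    # rotation about z fixes the z reference axis
    ribos2 <- PoseSet(rbind(c(1, 0, 0)),
                      array(R %*% rotZ(90), c(3, 3, 1)))
    pr2 <- pairNearest(ribos2, vaults)
    expect_equal(drop(relativeAxis(pr2, c(0, 0, 1))), c(0, 0, 1),
                 tolerance = 1e-12)
})

test_that("spherical histograms cover the sphere and count correctly", {
    sh <- sphericalHistogram(matrix(c(0, 0, 1), 1, 3), nSubdiv = 1)
    expect_equal(length(sh$counts), 80)
    expect_equal(sum(sh$counts), 1)
    same <- sphericalHistogram(matrix(rep(c(1, 2, 2) / 3, 50), 50, 3,
                                      byrow = TRUE), 1)
    expect_equal(max(same$counts), 50)
    expect_equal(sum(same$counts > 0), 1)
    empty <- sphericalHistogram(matrix(numeric(0), 0, 3), 1)
    expect_equal(sum(empty$counts), 0)
    expect_equal(empty$total, 0)
    expect_error(sphericalHistogram(rbind(c(0, 0, 0)), 1), "zero-length")
})

test_that("uniform directions fill icosahedral bins near-evenly", {
    set.seed(10)
    x <- matrix(rnorm(3e5), ncol = 3)
    sh <- sphericalHistogram(x, nSubdiv = 1)
    expect_lt(max(sh$counts) / min(sh$counts), 1.5)
})

test_that("RTC classification thresholds the relative angle inclusively", {
    R <- diag(3)
    vaults <- PoseSet(rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0)),
                      array(R, c(3, 3, 3)))
    rot <- array(0, c(3, 3, 3))
    rot[, , 1] <- diag(3)              # aligned
    rot[, , 2] <- rotX(90)             # perpendicular
    rot[, , 3] <- rotX(30)             # exactly at the threshold
    ribos <- PoseSet(rbind(c(1, 0, 0), c(101, 0, 0), c(201, 0, 0)), rot)
    pr <- pairNearest(ribos, vaults)
    lab <- classifyRTC(pr, thetaRtc = 30)
    expect_equal(as.character(lab), c("RTC-like", "other", "RTC-like"))
})

test_that("orientation contingency reproduces the printed Fisher result", {
    membrane <- c(rep(TRUE, 3), FALSE)          # 3 RTC-like, 1 not
    cytosolic <- rep(FALSE, 80)                 # 0 RTC-like, 80 not
    res <- orientationContingency(membrane, cytosolic)
    expect_equal(as.vector(res$table), c(3L, 0L, 1L, 80L))
    expect_lt(res$test$p_value, 1e-4)
    expect_equal(res$test$p_value, fisherEnumOracle(3, 1, 0, 80),
                 tolerance = 1e-9)
    flat <- orientationContingency(c(TRUE, FALSE), c(TRUE, FALSE))
    expect_equal(flat$test$p_value, 1)
    expect_error(orientationContingency(logical(0), cytosolic),
                 "non-empty")
})

test_that("encapsulation summary reproduces the printed percentages", {
    vaultClasses <- rep(c("cytosolic", "membrane"), c(985, 14))
    paired <- c(seq_len(80), 985 + seq_len(4))  # 80/985 and 4/14
    pairs <- data.frame(ribosomeIndex = seq_along(paired),
                        vaultIndex = paired)
    res <- encapsulationSummary(vaultClasses, pairs)
    expect_equal(res$summary$percent[res$summary$class == "cytosolic"], 8)
    expect_equal(res$summary$percent[res$summary$class == "membrane"], 29)
    expect_equal(round(res$test$p_value, 4), 0.0242)
    expect_error(encapsulationSummary(c("cytosolic", NA), pairs),
                 "classified")
})

test_that("class fractions round to one decimal", {
    vc <- rep(c("cytosolic", "membrane"), c(985, 14))
    cf <- classFractionSummary(vc)
    expect_equal(cf$percent[cf$class == "membrane"], 1.4)
    expect_equal(classFractionSummary(rep("x", 999))$percent, 100)
    one <- classFractionSummary(c(rep("a", 999)))
    expect_equal(one$n, 999)
})

test_that("concentrated populations concentrate histogram mass, uniform
           populations do not", {
    tgt <- sphericalHistogram(matrix(numeric(0), 0, 3),
                              1)$binDirections[1, ]
    conc <- makePosePopulation(populationSpec(nVaultsCytosolic = 60,
                                              encapsulationFraction = 1,
                                              kappa = 400,
                                              targetAxis = tgt,
                                              nFreeRibosomes = 0,
                                              boxExtent = 600, seed = 3))
    pc <- pairNearest(conc$ribosomes, conc$vaults)
    shc <- sphericalHistogram(relativeAxis(pc), 1)
    expect_gt(max(shc$counts) / shc$total, 0.8)
    unif <- makePosePopulation(populationSpec(
        nVaultsCytosolic = 60, encapsulationFraction = 1,
        relativeOrientationMode = "uniform", nFreeRibosomes = 0,
        boxExtent = 600, seed = 4))
    pu <- pairNearest(unif$ribosomes, unif$vaults)
    shu <- sphericalHistogram(relativeAxis(pu), 1)
    expect_lt(max(shu$counts) / shu$total, 0.3)
})
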