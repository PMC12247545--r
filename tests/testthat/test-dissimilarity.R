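test_that("pattern distance has the analytic values on unit directions", {
    v <- rnorm(20)
    expect_identical(patternDistance(v, v), 0)
    expect_equal(patternDistance(v, -v), 2)
    expect_equal(patternDistance(c(1, 0), c(0, 1)), sqrt(2),
                 tolerance = 1e-12)
    # scale invariance under normalisation
    w <- rnorm(20)
    expect_equal(patternDistance(v, w), patternDistance(3.7 * v, 0.2 * w),
                 tolerance = 1e-12)
    # raw distance without normalisation
    expect_equal(patternDistance(c(3, 0), c(0, 4), normalize = FALSE), 5)
    # degenerate zero-norm pattern flags NaN
    expect_true(is.nan(patternDistance(rep(0, 5), v[1:5])))
    expect_error(patternDistance(1:3, 1:4), "equal length")
})

test_that("distance equals sqrt(2 - 2 cos(theta)) for normalised vectors", {
    set.seed(17)
    for (i in 1:50) {
        a <- rnorm(15)
        b <- rnorm(15)
        cosT <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
        expect_equal(patternDistance(a, b), sqrt(2 - 2 * cosT),
                     tolerance = 1e-9)
    }
})

test_that("metric axioms hold on sphere patterns", {
    set.seed(23)
    for (i in 1:25) {
        a <- rnorm(10); b <- rnorm(10); cc <- rnorm(10)
        dab <- patternDistance(a, b)
        expect_equal(dab, patternDistance(b, a), tolerance = 1e-12)
        expect_identical(patternDistance(a, a), 0)
        expect_lte(dab, patternDistance(a, cc) + patternDistance(cc, b) +
                       1e-12)
    }
})

test_that("identical condition maps give identically-zero contrast maps", {
    g <- deskGrid(10)
    set.seed(5)
    z <- matrix(rnorm(nMaskVoxels(g)), ncol = 1)
    vals <- cbind(z, z, matrix(rnorm(nMaskVoxels(g)), ncol = 1))
    m <- conditionMaps(vals, g, rep("s1", 3),
                       c("pain", "touch", "control"))
    dm <- dissimilaritySearchlight(m, sphereOffsets(2))
    pt <- assay(dm)[, colData(dm)$contrast == "pain_vs_touch"]
    expect_true(all(pt == 0))
    pc <- assay(dm)[, colData(dm)$contrast == "pain_vs_control"]
    expect_gt(max(pc), 0)
})

test_that("orthogonal templates at negligible noise give sqrt(2) in-ROI", {
    g <- deskGrid(12)
    coh <- templateCohort(3, g, c(4, 4, 4), c(9, 9, 9),
                          noiseSD = 1, signalScale = 100, seed = 77)
    dm <- dissimilaritySearchlight(coh$maps, sphereOffsets(2))
    inner <- match(roiBlock(g, c(6, 6, 6), c(8, 8, 8)), maskIndices(g))
    v <- assay(dm)[inner, ]
    # sub-sphere patterns of orthogonal templates scatter around sqrt(2)
    # with sd ~ 1/sqrt(2 p) from the sub-pattern angle fluctuation
    expect_equal(mean(v), sqrt(2), tolerance = 0.05)
    expect_true(all(abs(v - sqrt(2)) < 0.5))
})

test_that("all dissimilarities on synthetic cohorts stay within [0, 2]", {
    g <- deskGrid(10)
    coh <- generateCohort(syntheticConfig(nSubjects = 6, grid = g,
                                          seed = 85))
    dm <- dissimilaritySearchlight(coh$maps, sphereOffsets(2))
    v <- assay(dm)
    expect_true(all(v[!is.nan(v)] >= 0 & v[!is.nan(v)] <= 2))
    expect_identical(ncol(dm), 18L) # 3 contrast maps per subject
})

test_that("group mean reduces to the single subject's map", {
    g <- deskGrid(8)
    coh <- generateCohort(syntheticConfig(nSubjects = 1, grid = g,
                                          seed = 3))
    dm <- dissimilaritySearchlight(coh$maps, sphereOffsets(1))
    gm <- groupMeanDissimilarity(dm, "pain_vs_touch")
    expect_equal(slValues(gm),
                 unname(assay(dm)[, colData(dm)$contrast == "pain_vs_touch"]))
})

test_that("peak tables report seeded separation maxima, empty when flat", {
    # flat zero map: nothing above the display threshold
    g <- deskGrid(10)
    zero <- new("SearchlightResult", values = rep(0, nMaskVoxels(g)),
                grid = g, statisticName = "x", radius = 2)
    expect_identical(nrow(reportPeaks(zero, threshold = 1.5)), 0L)
    # designed separation 1.8 at high SNR: group-mean peak near 1.8 in-ROI
    g2 <- deskGrid(12)
    coh <- templateCohort(6, g2, c(4, 4, 4), c(9, 9, 9),
                          noiseSD = 1, signalScale = 60, seed = 91,
                          baseSep = 1.8, subjectSD = 0.01)
    dm <- dissimilaritySearchlight(coh$maps, sphereOffsets(2))
    gm <- groupMeanDissimilarity(dm, "pain_vs_control")
    # all group-mean distances respect the [0, 2] bound
    expect_true(all(slValues(gm)[!is.na(slValues(gm))] <= 2 + 1e-12))
    # peak search over the region where spheres sit fully inside the seeded
    # block recovers the designed separation
    core <- roiBlock(g2, c(6, 6, 6), c(7, 7, 7))
    vol <- as.array(gm)
    restricted <- array(NA_real_, dim(vol))
    restricted[core] <- vol[core]
    pk <- reportPeaks(restricted, threshold = 1.5)
    expect_gt(nrow(pk), 0)
    expect_equal(pk$value[1], 1.8, tolerance = 0.06)
    roiCC <- arrayInd(coh$voxels, gridShape(g2)) - 1L
    expect_true(any(roiCC[, 1] == pk$x[1] & roiCC[, 2] == pk$y[1] &
                        roiCC[, 3] == pk$z[1]))
})

test_that("degenerate all-zero spheres yield NaN, excluded from means", {
    g <- cubeGrid(8)
    vals <- matrix(0, 512, 3)
    vals[200:512, ] <- rnorm(313 * 3)
    m <- conditionMaps(vals, g, rep("s1", 3),
                       c("pain", "touch", "control"))
    dm <- dissimilaritySearchlight(m, sphereOffsets(1))
    v <- assay(dm)[, 1]
    expect_true(any(is.nan(v)))
    gm <- groupMeanDissimilarity(dm, "pain_vs_touch")
    expect_true(all(is.na(slValues(gm)[is.nan(v)])))
})
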