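condLabels <- function(n) rep(c("pain", "touch", "control"), n)
subjGroups <- function(n) rep(sprintf("s%02d", seq_len(n)), each = 3)

test_that("perfectly separable cohorts are decoded at accuracy 1", {
    # identical orthogonal unit templates across subjects, zero noise
    n <- 10
    X <- do.call(rbind, replicate(n, diag(3), simplify = FALSE)) * 4
    expect_identical(losoAccuracy(X, condLabels(n), subjGroups(n)), 1)
    # two subjects, one voxel: pain +1, touch 0, control -1
    X2 <- matrix(c(1, 0, -1, 1, 0, -1), ncol = 1)
    expect_identical(losoAccuracy(X2, condLabels(2), subjGroups(2)), 1)
})

test_that("accuracy is invariant to a common affine rescaling of features", {
    set.seed(41)
    n <- 8
    X <- do.call(rbind, replicate(n, diag(3) + matrix(rnorm(9, sd = 0.8),
                                                      3), simplify = FALSE))
    a1 <- losoAccuracy(X, condLabels(n), subjGroups(n))
    a2 <- losoAccuracy(X * 37.5, condLabels(n), subjGroups(n))
    expect_identical(a1, a2)
    expect_gt(a1, 1 / 3)
})

test_that("permuting labels within subjects destroys decodability", {
    g <- deskGrid(10)
    coh <- templateCohort(12, g, c(4, 4, 4), c(7, 7, 7), noiseSD = 1,
                          signalScale = 2, seed = 51)
    cd <- colData(coh$maps)
    X <- t(assay(coh$maps)[match(coh$voxels, maskIndices(g)), ])
    labs <- as.character(cd$condition)
    groups <- as.character(cd$subject)
    accTrue <- losoAccuracy(X, labs, groups)
    expect_gt(accTrue, 0.8)
    set.seed(7)
    accNull <- vapply(1:10, function(i) {
        shuffled <- labs
        for (ix in split(seq_along(labs), groups))
            shuffled[ix] <- labs[ix][sample(3)]
        losoAccuracy(X, shuffled, groups)
    }, numeric(1))
    # mean over shuffles within 2 SE of chance (n = 36 predictions each)
    se <- sqrt((1 / 3) * (2 / 3) / (36 * 10))
    expect_lt(abs(mean(accNull) - 1 / 3), 3 * se + 0.05)
})

test_that("fold structure holds: each subject tested once, 3 predictions", {
    # accuracy denominators: a dataset where exactly one subject is
    # decodable gives accuracy k/(3n) with k a multiple of 1 up to 3
    n <- 5
    X <- do.call(rbind, replicate(n, diag(3) * 0, simplify = FALSE))
    set.seed(2)
    X <- X + matrix(rnorm(length(X), sd = 1e-3), nrow(X))
    acc <- losoAccuracy(X, condLabels(n), subjGroups(n))
    expect_true(abs(acc * (3 * n) - round(acc * 3 * n)) < 1e-12)
    expect_error(losoAccuracy(X[1:3, ], condLabels(1), subjGroups(1)),
                 "at least 2 subjects")
    expect_error(losoAccuracy(X[, 0], condLabels(n), subjGroups(n)),
                 "undefined sphere")
})

test_that("classification searchlight peaks inside the seeded region", {
    g <- volumeGrid(c(16, 16, 16), mask = ellipsoidMask(c(16, 16, 16)))
    coh <- templateCohort(10, g, c(4, 4, 4), c(8, 8, 8), noiseSD = 1,
                          signalScale = 1.5, seed = 61)
    # inner ROI centres (sphere radius 2 stays mostly inside)
    inner <- match(roiBlock(g, c(5, 5, 5), c(7, 7, 7)), maskIndices(g))
    # far field: centres whose spheres cannot touch the seeded block
    mi <- maskIndices(g)
    cc <- arrayInd(mi, gridShape(g))
    dist2roi <- pmax(0, 4 - cc[, 1], cc[, 1] - 8)^2 +
        pmax(0, 4 - cc[, 2], cc[, 2] - 8)^2 +
        pmax(0, 4 - cc[, 3], cc[, 3] - 8)^2
    far <- which(dist2roi > (2 + 1)^2)
    set.seed(3)
    outSample <- sample(far, 25)
    sl <- classificationSearchlight(coh$maps, sphereOffsets(2),
                                    centers = c(inner, outSample))
    v <- slValues(sl)
    expect_gt(max(v[inner]), 0.75)
    # far-field spheres decode at chance
    se <- sqrt((1 / 3) * (2 / 3) / 30)
    expect_lt(abs(mean(v[outSample]) - 1 / 3), 3 * se)
    expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
})

test_that("all-identical condition templates carry no class information", {
    g <- deskGrid(10)
    vox <- roiBlock(g, c(4, 4, 4), c(7, 7, 7))
    set.seed(9)
    tm <- matrix(rep(rnorm(length(vox)), 3), ncol = 3) # same template x3
    cfg <- syntheticConfig(nSubjects = 10, grid = g,
                           rois = list(list(voxels = vox, templates = tm)),
                           signalScale = 2, seed = 71)
    coh <- generateCohort(cfg)
    rows <- match(vox, maskIndices(g))[1:10]
    sl <- classificationSearchlight(coh$maps, sphereOffsets(2),
                                    centers = rows)
    accs <- slValues(sl)[rows]
    se <- sqrt((1 / 3) * (2 / 3) / 30)
    expect_lt(abs(mean(accs) - 1 / 3), 3 * se)
})

test_that("missing conditions are a dataset error", {
    g <- deskGrid(8)
    z <- matrix(rnorm(nMaskVoxels(g) * 5), ncol = 5)
    m <- conditionMaps(z, g, c("a", "a", "a", "b", "b"),
                       c("pain", "touch", "control", "pain", "touch"))
    expect_error(classificationSearchlight(m), "dataset error")
})
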