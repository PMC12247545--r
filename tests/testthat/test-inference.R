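test_that("voxelwise correlation reproduces perfect and null cases", {
    # perfect positive: t capped at the documented ceiling
    M <- matrix(c(1, 2, 3), nrow = 1)
    expect_identical(voxelwiseCorrelation(M, c(2, 4, 6)), 1e4)
    expect_identical(voxelwiseCorrelation(M, c(6, 4, 2)), -1e4)
    expect_equal(voxelwiseCorrelation(M, c(2, 4, 6), statistic = "r"), 1)
    expect_equal(voxelwiseCorrelation(M, c(6, 4, 2), statistic = "r"), -1)
    # zero-variance voxels get statistic 0
    M2 <- rbind(c(5, 5, 5, 5), rnorm(4))
    expect_identical(voxelwiseCorrelation(M2, c(1, 2, 3, 4))[1], 0)
    # degenerate covariate errors
    expect_error(voxelwiseCorrelation(M2, rep(2, 4)),
                 "degenerate covariate")
    # demeaning the trait does not change the statistic
    set.seed(1)
    M3 <- matrix(rnorm(40), nrow = 10)
    tr <- rnorm(4) + 10
    expect_equal(voxelwiseCorrelation(M3, tr),
                 voxelwiseCorrelation(M3, tr - mean(tr)))
})

test_that("null per-voxel correlations have the n-subject sampling spread", {
    set.seed(101)
    n <- 70
    M <- matrix(rnorm(3000 * n), ncol = n)
    r <- voxelwiseCorrelation(M, rnorm(n), statistic = "r")
    expect_lt(abs(mean(r)), 0.01)
    expect_equal(sd(r), 1 / sqrt(n - 1), tolerance = 0.05)
})

test_that("observed map among its own null bounds the inverse p", {
    g <- deskGrid(8)
    set.seed(7)
    n <- 10
    M <- matrix(rnorm(nMaskVoxels(g) * n), ncol = n)
    r <- permutationFWE(M, rnorm(n), grid = g, nPerm = 99, seed = 5)
    expect_true(all(fweInvP(r) <= 99 / 100 + 1e-12))
    expect_true(all(fweInvP(r) >= 0))
    expect_identical(r@nPerm, 99L)
})

test_that("relabelling subjects consistently leaves FWE p unchanged", {
    g <- deskGrid(8)
    set.seed(11)
    n <- 12
    M <- matrix(rnorm(nMaskVoxels(g) * n), ncol = n)
    tr <- rnorm(n)
    perm <- sample(n)
    r1 <- permutationFWE(M, tr, grid = g, nPerm = 60, seed = 9)
    r2 <- permutationFWE(M[, perm], tr[perm], grid = g, nPerm = 60,
                         seed = 9)
    expect_equal(fweInvP(r1), fweInvP(r2), tolerance = 1e-12)
    expect_equal(statValues(r1), statValues(r2), tolerance = 1e-12)
})

test_that("exhaustive enumeration recovers the exact permutation p", {
    # tiny design: brute-force Fisher-Pitman oracle over all n! shuffles
    g <- cubeGrid(4)
    set.seed(13)
    n <- 5
    M <- matrix(rnorm(64 * n, sd = 1), ncol = n)
    M[1:5, ] <- M[1:5, ] + outer(rep(1, 5), seq_len(n)) # coupled voxels
    tr <- seq_len(n) + rnorm(n, sd = 0.1)
    expect_warning(
        res <- permutationFWE(M, tr, grid = g, nPerm = 1000, seed = 3,
                              params = tfceParams(dh = 0.5)),
        "exhaustively")
    expect_identical(res@nPerm, 120L)
    # independent oracle: enumerate permutations, recompute t + TFCE in R
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(p) all(sort(p) == 1:n)), ]
    tstat <- function(y) {
        yc <- y - mean(y)
        vapply(seq_len(nrow(M)), function(v) {
            x <- M[v, ]
            r <- sum((x - mean(x)) * yc) /
                sqrt(sum((x - mean(x))^2) * sum(yc^2))
            r * sqrt((n - 2) / (1 - r^2))
        }, numeric(1))
    }
    obs <- tstat(tr)
    dh <- 0.5
    tfceOf <- function(s) {
        vol <- array(pmax(s, 0), c(4, 4, 4))
        referenceTFCE(vol, 0.5, 2, dh, 26)
    }
    obsT <- tfceOf(obs)
    maxNull <- apply(perms, 1, function(p) max(tfceOf(tstat(tr[p]))))
    pOracle <- vapply(as.vector(obsT)[maskIndices(g)], function(v)
        mean(maxNull >= v - 1e-12), numeric(1))
    expect_equal(fweInvP(res), 1 - pOracle, tolerance = 1e-10)
})

test_that("the full correlation battery covers 3 x 4 x 2 tests", {
    g <- deskGrid(8)
    coh <- generateCohort(syntheticConfig(nSubjects = 6, grid = g,
                                          seed = 19))
    dm <- dissimilaritySearchlight(coh$maps, sphereOffsets(1))
    res <- runEmpathyCorrelations(dm, coh$traits, nPerm = 25, seed = 2)
    expect_length(res, 24L)
    expect_identical(sum(vapply(res, function(r) r@direction,
                                "") == "positive"), 12L)
    expect_setequal(
        unique(vapply(res, function(r) r@label, "")),
        as.vector(outer(c("pain_vs_touch", "pain_vs_control",
                          "touch_vs_control"),
                        c("FS", "EC", "PT", "PD"), paste, sep = "~")))
    summ <- summarizeStatResults(res)
    expect_identical(nrow(summ), 24L)
    # subject mismatch is an alignment error
    badTraits <- coh$traits
    badTraits$subject_id[1] <- "nope"
    expect_error(runEmpathyCorrelations(dm, badTraits, nPerm = 5),
                 "alignment error")
    # constant traits are a degenerate covariate
    cst <- coh$traits
    cst$EC <- 7
    expect_error(runEmpathyCorrelations(dm, cst, nPerm = 5,
                                        subscales = "EC"),
                 "degenerate covariate")
})
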