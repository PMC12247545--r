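test_that("resel estimators divide the mask by the sphere footprint", {
    sp3 <- sphereOffsets(3)
    mk <- function(n) {
        m <- array(FALSE, c(20, 20, 20))
        m[seq_len(n)] <- TRUE
        m
    }
    expect_identical(reselCount(mk(123), sp3), 1L)
    expect_identical(reselCount(mk(1230), sp3), 10L)
    expect_identical(reselCount(mk(1000), sp3, method = "cube"), 2L)
    expect_error(reselCount(array(FALSE, c(3, 3, 3)), sp3), "empty mask")
})

test_that("Bonferroni alpha is a straight division", {
    expect_equal(bonferroniAlpha(0.05, 725), 6.896552e-05,
                 tolerance = 1e-6)
    expect_identical(bonferroniAlpha(0.05, 1), 0.05)
    expect_identical(bonferroniAlpha(0.01, 10), 0.001)
    expect_error(bonferroniAlpha(1.2, 10), "in \\(0, 1\\)")
})

test_that("the reference decoding threshold is reproduced", {
    bt <- binomialThreshold(210, 1 / 3, bonferroniAlpha(0.05, 725))
    expect_identical(bt$kCritical, 97L)
    expect_equal(round(100 * bt$accuracyCritical), 46)
    # under the strict own-tail convention the count is one higher
    btTail <- binomialThreshold(210, 1 / 3, bonferroniAlpha(0.05, 725),
                                convention = "tail")
    expect_identical(btTail$kCritical, 98L)
})

test_that("binomial threshold edge cases and the strict-tail example", {
    # alpha = 1: every accuracy passes
    expect_identical(binomialThreshold(50, 0.5, 1)$kCritical, 0L)
    expect_identical(binomialThreshold(50, 0.5, 1,
                                       convention = "tail")$kCritical, 0L)
    # strict-tail example: P(X>=9)=11/1024 <= 0.05 < P(X>=8)=56/1024
    bt <- binomialThreshold(10, 0.5, 0.05, convention = "tail")
    expect_identical(bt$kCritical, 9L)
    expect_true(bt$attainable)
    # unattainably small alpha under the strict convention
    btU <- binomialThreshold(10, 0.5, 1e-12, convention = "tail")
    expect_false(btU$attainable)
    expect_identical(btU$kCritical, 11L)
})

test_that("both conventions agree with brute-force tail summation", {
    for (n in c(10, 60, 210, 500)) {
        for (p in c(1 / 3, 0.5)) {
            for (alpha in c(0.05, 1e-3, 6.9e-5)) {
                got <- binomialThreshold(n, p, alpha)
                # oracle for invcdf: smallest k with P(X > k) <= alpha
                kI <- 0L
                while (kI <= n && bruteUpperTail(kI + 1L, n, p) > alpha)
                    kI <- kI + 1L
                expect_identical(got$kCritical, kI)
                gotT <- binomialThreshold(n, p, alpha, convention = "tail")
                kT <- 0L
                while (kT <= n && bruteUpperTail(kT, n, p) > alpha)
                    kT <- kT + 1L
                expect_identical(gotT$kCritical, kT)
                expect_equal(got$accuracyCritical, kI / n)
            }
        }
    }
})

test_that("threshold is monotone in alpha and n", {
    ks <- vapply(c(0.05, 1e-2, 1e-3, 1e-4, 1e-5), function(a)
        binomialThreshold(210, 1 / 3, a)$kCritical, integer(1))
    expect_true(all(diff(ks) >= 0))
    accs <- vapply(c(30, 60, 210, 1000, 5000), function(n)
        binomialThreshold(n, 1 / 3, 1e-4)$accuracyCritical, numeric(1))
    expect_true(all(diff(accs) <= 1e-12))
    expect_gt(min(accs), 1 / 3)
})

test_that("accuracy maps threshold inclusively at k/n", {
    g <- deskGrid(8)
    spec <- thresholdSpec(210, resels = 725)
    nv <- nMaskVoxels(g)
    vals <- rep(1 / 3, nv)
    vals[5] <- 97 / 210
    vals[6] <- 96 / 210
    acc <- new("SearchlightResult", values = vals, grid = g,
               statisticName = "loso_accuracy", radius = 3)
    thr <- thresholdAccuracyMap(acc, spec)
    mi <- maskIndices(g)
    expect_true(thr[mi[5]])   # exactly k/n is significant (inclusive)
    expect_false(thr[mi[6]])  # one fewer correct is not
    expect_identical(sum(thr), 1L)
    expect_false(any(thr[!brainMask(g)]))
})

test_that("threshold specs serialise with all reported fields", {
    spec <- thresholdSpec(210, resels = 725)
    f <- tempfile(fileext = ".json")
    writeThresholdSpec(spec, f)
    back <- jsonlite::read_json(f)
    expect_identical(back$k_critical, 97L)
    expect_identical(back$resel_count, 725L)
    expect_equal(back$alpha_corrected, 0.05 / 725, tolerance = 1e-12)
    unlink(f)
})
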