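#' Resel count: non-overlapping searchlight spheres fitting in the mask
#'
#' Estimates the effective number of independent tests for the resel-wise
#' Bonferroni correction of an accuracy map as the number of
#' non-overlapping spheres that fit in the brain mask. The default
#' estimator divides the mask voxel count by the sphere voxel count; the
#' `"cube"` estimator packs axis-aligned cubes of edge `2*floor(r) + 1`
#' instead. Both are deterministic; the count is always reportable and can
#' be overridden downstream (the reference value on the standard MNI brain
#' mask at radius 3 is ~725).
#'
#' @param grid a [VolumeGrid-class] (its mask is used), or a logical array.
#' @param sphere a [SphereSpec-class].
#' @param method `"sphere"` (default) or `"cube"`.
#' @return positive integer.
#' @examples
#' reselCount(volumeGrid(c(10, 10, 10)), sphereOffsets(3)) # floor(1000/123)
#' @export
reselCount <- function(grid, sphere = sphereOffsets(3),
                       method = c("sphere", "cube")) {
    method <- match.arg(method)
    mask <- if (is(grid, "VolumeGrid")) brainMask(grid) else grid
    nm <- sum(mask)
    if (nm == 0L) stop("empty mask")
    denom <- switch(method,
        sphere = nSphereVoxels(sphere),
        cube = (2L * floor(sphereRadius(sphere)) + 1L)^3
    )
    max(1L, as.integer(floor(nm / denom)))
}

#' Bonferroni-corrected alpha over resels
#'
#' @param alphaNominal nominal family-wise alpha in (0, 1).
#' @param resels positive resel count.
#' @return `alphaNominal / resels`.
#' @examples
#' bonferroniAlpha(0.05, 725) # 6.90e-05
#' @export
bonferroniAlpha <- function(alphaNominal, resels) {
    if (alphaNominal <= 0 || alphaNominal >= 1)
        stop("alphaNominal must be in (0, 1)")
    if (resels < 1) stop("resels must be >= 1")
    alphaNominal / resels
}

#' Critical classification count under the exact binomial null
#'
#' Finds the accuracy threshold that is significant at `alpha` when each of
#' `n` classifications succeeds with probability `chanceP` under the null.
#' Two conventions are provided:
#'
#' * `"invcdf"` (default): the binomial inverse-CDF value, the smallest k
#'   with `P(X <= k) >= 1 - alpha` (equivalently `P(X > k) <= alpha`). This
#'   is what `binoinv`-style functions return and reproduces the reference
#'   threshold 97/210 (46%) at `alpha = 0.05/725` for chance 1/3.
#' * `"tail"`: the smallest k whose own upper-tail probability
#'   `P(X >= k)` does not exceed `alpha` (one unit above the inverse-CDF
#'   value whenever `P(X >= k_invcdf) > alpha`).
#'
#' Tail probabilities use exact binomial sums evaluated in log space, so
#' alphas of order 1e-5 and far smaller are handled without underflow.
#'
#' @param n number of classifications (e.g. subjects x conditions).
#' @param chanceP chance success probability in (0, 1).
#' @param alpha significance level in (0, 1].
#' @param convention `"invcdf"` or `"tail"`.
#' @return list with `kCritical`, `accuracyCritical` (= k/n) and
#'   `attainable` (`FALSE`, with `kCritical = n + 1`, when even k = n is
#'   not significant under the `"tail"` convention).
#' @examples
#' binomialThreshold(210, 1/3, 0.05 / 725) # k = 97, accuracy ~ 46%
#' @export
binomialThreshold <- function(n, chanceP, alpha,
                              convention = c("invcdf", "tail")) {
    convention <- match.arg(convention)
    if (n < 1) stop("n must be >= 1")
    if (chanceP <= 0 || chanceP >= 1) stop("chanceP must be in (0, 1)")
    if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
    # log upper-tail P(X >= k)
    uppertail <- function(k) {
        if (k <= 0) return(0) # log(1)
        # far tails underflow to -Inf, which is the correct limiting value
        suppressWarnings(
            pbinom(k - 1, n, chanceP, lower.tail = FALSE, log.p = TRUE))
    }
    if (convention == "invcdf") {
        # smallest k with P(X > k) <= alpha
        k <- 0L
        while (k <= n && uppertail(k + 1L) > log(alpha)) k <- k + 1L
        attainable <- TRUE
    } else {
        k <- 0L
        while (k <= n && uppertail(k) > log(alpha)) k <- k + 1L
        attainable <- k <= n
    }
    list(kCritical = as.integer(k), accuracyCritical = k / n,
         attainable = attainable)
}

#' Assemble the full significance specification for an accuracy map
#'
#' Combines [reselCount()], [bonferroniAlpha()] and [binomialThreshold()]
#' into a [ThresholdSpec-class]. `resels` may be given explicitly (e.g. the
#' reference 725 for the standard MNI brain) or derived from a grid.
#'
#' @param nClassifications binomial n (subjects x conditions).
#' @param grid a [VolumeGrid-class] used to derive the resel count when
#'   `resels` is not given.
#' @param sphere a [SphereSpec-class].
#' @param resels explicit resel count overriding the estimator.
#' @param chanceP chance level (default 1/3).
#' @param alphaNominal nominal alpha (default 0.05).
#' @inheritParams binomialThreshold
#' @return A [ThresholdSpec-class].
#' @examples
#' thresholdSpec(210, resels = 725)
#' @export
thresholdSpec <- function(nClassifications, grid = NULL,
                          sphere = sphereOffsets(3), resels = NULL,
                          chanceP = 1 / 3, alphaNominal = 0.05,
                          convention = c("invcdf", "tail")) {
    convention <- match.arg(convention)
    if (is.null(resels)) {
        if (is.null(grid)) stop("either 'resels' or 'grid' is required")
        resels <- reselCount(grid, sphere)
    }
    alphaC <- bonferroniAlpha(alphaNominal, resels)
    bt <- binomialThreshold(nClassifications, chanceP, alphaC,
                            convention = convention)
    new("ThresholdSpec",
        alphaNominal = alphaNominal, reselCount = as.integer(resels),
        alphaCorrected = alphaC,
        nClassifications = as.integer(nClassifications), chanceP = chanceP,
        kCritical = bt$kCritical, accuracyCritical = bt$accuracyCritical,
        attainable = bt$attainable, convention = convention)
}

setMethod("show", "ThresholdSpec", function(object) {
    cat(sprintf(
        paste0("ThresholdSpec: alpha %.3g / %d resels = %.4g; ",
               "binomial n=%d, chance=%.4g -> k >= %d (accuracy %.1f%%)%s\n"),
        object@alphaNominal, object@reselCount, object@alphaCorrected,
        object@nClassifications, object@chanceP, object@kCritical,
        100 * object@accuracyCritical,
        if (object@attainable) "" else " [unattainable]"))
})

#' Threshold an accuracy map at the binomial critical accuracy
#'
#' @param acc a [SearchlightResult-class] of accuracies (or a 3D array).
#' @param spec a [ThresholdSpec-class].
#' @return logical 3D array, `TRUE` exactly where accuracy >=
#'   `accuracyCritical` (inclusive); `FALSE` outside the mask.
#' @export
thresholdAccuracyMap <- function(acc, spec) {
    vol <- if (is(acc, "SearchlightResult")) as.array(acc) else acc
    out <- !is.na(vol) & vol >= spec@accuracyCritical - 1e-12
    array(out, dim = dim(vol))
}

#' Serialise a ThresholdSpec to JSON
#'
#' @param spec a [ThresholdSpec-class].
#' @param path output file.
#' @export
writeThresholdSpec <- function(spec, path) {
    jsonlite::write_json(list(
        alpha_nominal = spec@alphaNominal,
        resel_count = spec@reselCount,
        alpha_corrected = spec@alphaCorrected,
        n_classifications = spec@nClassifications,
        chance_p = spec@chanceP,
        k_critical = spec@kCritical,
        accuracy_critical = spec@accuracyCritical,
        attainable = spec@attainable,
        convention = spec@convention
    ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
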