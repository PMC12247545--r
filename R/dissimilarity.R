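#' Euclidean distance between two pattern vectors
#'
#' With `normalize = TRUE` (the default) each vector is first scaled to
#' unit Euclidean norm, so the distance is bounded by [0, 2]: identical
#' patterns give 0, orthogonal patterns sqrt(2), antipodal patterns 2
#' (equivalently `sqrt(2 - 2 cos theta)` where theta is the angle between
#' the patterns). With `normalize = FALSE` the raw Euclidean distance is
#' returned. A zero-norm vector under normalisation is a degenerate
#' pattern: the value is `NaN` so downstream inference can exclude the
#' voxel.
#'
#' @param v1,v2 numeric vectors of equal length >= 1.
#' @param normalize scale both vectors to unit norm first (default TRUE).
#' @return a single distance.
#' @examples
#' patternDistance(c(1, 0), c(0, 1)) # sqrt(2)
#' patternDistance(c(1, 1), c(-1, -1)) # 2
#' @export
patternDistance <- function(v1, v2, normalize = TRUE) {
    if (length(v1) != length(v2) || length(v1) < 1L)
        stop("v1 and v2 must have equal length >= 1")
    if (normalize) {
        n1 <- sqrt(sum(v1^2))
        n2 <- sqrt(sum(v2^2))
        if (n1 == 0 || n2 == 0) return(NaN)
        v1 <- v1 / n1
        v2 <- v2 / n2
    }
    sqrt(sum((v1 - v2)^2))
}

#' Per-subject Euclidean pattern-dissimilarity searchlight
#'
#' For every subject and every brain-mask voxel, vectorises the z-statistic
#' values of the three condition maps inside the searchlight sphere and
#' computes the pairwise Euclidean distances between the (unit-normalised)
#' condition pattern vectors, mapping each distance to the sphere centre.
#' This yields three dissimilarity maps per subject — `pain_vs_touch`,
#' `pain_vs_control`, `touch_vs_control` — with values between 0 and 2.
#' All computation is within-subject; no cross-subject pooling occurs.
#' Sphere membership (clipped at mask edges) is identical to the decoding
#' searchlight, sharing the same [SphereSpec-class].
#'
#' @param x a [ConditionMaps-class]; each subject needs all three
#'   conditions.
#' @param sphere a [SphereSpec-class] (default radius 3).
#' @param normalize unit-normalise sphere patterns first (default TRUE;
#'   this is what bounds the values by [0, 2]).
#' @param centers optional subset of mask-voxel indices; others are `NA`.
#' @return A [DissimilarityMaps-class] with `3 * nSubjects` columns.
#' @export
dissimilaritySearchlight <- function(x, sphere = sphereOffsets(3),
                                     normalize = TRUE, centers = NULL) {
    subjects <- .checkCompleteCohort(x)
    grid <- mapGrid(x)
    Z <- assay(x)
    cd <- colData(x)
    # column index per subject per condition
    colIdx <- sapply(.CONDITIONS, function(cn) {
        vapply(subjects, function(s)
            which(cd$subject == s & cd$condition == cn), integer(1))
    })
    if (is.null(dim(colIdx))) colIdx <- matrix(colIdx, nrow = 1L,
                                               dimnames = list(NULL,
                                                               .CONDITIONS))
    nbr <- .sphereRowIndex(grid, sphere)
    nC <- nrow(nbr)
    if (is.null(centers)) centers <- seq_len(nC)
    ns <- length(subjects)
    res <- lapply(.CONTRASTS, function(ct) matrix(NA_real_, nC, ns))
    names(res) <- .CONTRASTS
    pairIdx <- lapply(.CONTRASTS, .contrastPair)
    for (ci in centers) {
        rows <- nbr[ci, ]
        rows <- rows[rows > 0L]
        P <- Z[rows, , drop = FALSE]
        if (normalize) {
            nrm <- sqrt(colSums(P^2))
            nrm[nrm == 0] <- NaN # degenerate all-zero pattern -> NaN
            P <- sweep(P, 2L, nrm, "/")
        }
        for (k in seq_along(.CONTRASTS)) {
            pr <- pairIdx[[k]]
            D <- P[, colIdx[, pr[1]], drop = FALSE] -
                P[, colIdx[, pr[2]], drop = FALSE]
            d <- sqrt(colSums(D^2))
            if (normalize) d <- pmin(d, 2) # guard rounding above the bound
            res[[k]][ci, ] <- d
        }
    }
    values <- do.call(cbind, lapply(seq_along(.CONTRASTS), function(k)
        res[[k]]))
    subj <- rep(subjects, times = length(.CONTRASTS))
    contrast <- rep(.CONTRASTS, each = ns)
    colnames(values) <- paste(subj, contrast, sep = "_")
    se <- SummarizedExperiment(
        assays = list(dissimilarity = values),
        colData = DataFrame(subject = subj, contrast = contrast),
        metadata = list(grid = grid, radius = sphereRadius(sphere),
                        normalized = normalize)
    )
    new("DissimilarityMaps", se)
}

#' Voxelwise group mean of dissimilarity maps for one contrast
#'
#' @param x a [DissimilarityMaps-class].
#' @param contrast one of `pain_vs_touch`, `pain_vs_control`,
#'   `touch_vs_control`.
#' @return A [SearchlightResult-class] of across-subject mean distances
#'   (degenerate `NaN` voxels are excluded from the mean).
#' @export
groupMeanDissimilarity <- function(x, contrast) {
    contrast <- match.arg(contrast, .CONTRASTS)
    sel <- colData(x)$contrast == contrast
    if (!any(sel)) stop("no maps for contrast ", contrast)
    v <- assay(x)[, sel, drop = FALSE]
    m <- rowMeans(v, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    new("SearchlightResult", values = m, grid = mapGrid(x),
        statisticName = paste0("mean_dissimilarity_", contrast),
        radius = as.numeric(metadata(x)$radius %||% NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local maxima of a statistic volume above a threshold
#'
#' Reports voxels whose value is at least `threshold` and not smaller than
#' any of their 26 neighbours (plateau voxels tie and are all reported).
#'
#' @param x a [SearchlightResult-class] or 3D array.
#' @param threshold minimum reported value (default 1.5, the conventional
#'   display threshold for group-mean dissimilarity maps).
#' @return data.frame with 0-based voxel coordinates `x`, `y`, `z`, the
#'   world-space coordinates `x_mm`, `y_mm`, `z_mm` (when an affine is
#'   available), and `value`, sorted by decreasing value.
#' @export
reportPeaks <- function(x, threshold = 1.5) {
    grid <- if (is(x, "SearchlightResult")) x@grid else NULL
    vol <- if (is(x, "SearchlightResult")) as.array(x) else x
    dm <- dim(vol)
    cand <- which(!is.na(vol) & vol >= threshold)
    keep <- logical(length(cand))
    if (length(cand)) {
        off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
        off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
        cc <- arrayInd(cand, dm)
        for (i in seq_along(cand)) {
            v <- vol[cand[i]]
            nb <- sweep(off, 2L, cc[i, ], "+")
            ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
                nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
            w <- vol[nb[ok, , drop = FALSE]]
            keep[i] <- !any(w > v, na.rm = TRUE)
        }
    }
    cand <- cand[keep]
    cc <- arrayInd(cand, dm) - 1L # 0-based voxel coordinates
    out <- data.frame(x = cc[, 1], y = cc[, 2], z = cc[, 3],
                      value = vol[cand])
    if (!is.null(grid)) {
        mm <- cbind(cc, 1) %*% t(gridAffine(grid))
        out$x_mm <- mm[, 1]; out$y_mm <- mm[, 2]; out$z_mm <- mm[, 3]
        out <- out[, c("x", "y", "z", "x_mm", "y_mm", "z_mm", "value")]
    }
    out[order(-out$value), , drop = FALSE]
}
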