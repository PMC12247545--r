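#' TFCE parameter bundle
#'
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2.0). The (0.5, 2) pair is the
#'   standard published default for 3D volumetric statistics.
#' @param dh integration step in statistic units; `NA` (default) selects an
#'   adaptive step of (max statistic)/100 with a floor of 0.01.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A [TFCEParams-class].
#' @export
tfceParams <- function(E = 0.5, H = 2, dh = NA_real_, connectivity = 26L) {
    new("TFCEParams", E = E, H = H, dh = as.numeric(dh),
        connectivity = as.integer(connectivity))
}

#' Threshold-free cluster enhancement
#'
#' Enhances the positive part of a statistic volume:
#' `TFCE(v) = sum over h = dh, 2dh, ... <= stat(v) of e(h,v)^E * h^H * dh`,
#' where `e(h, v)` is the voxel count of the connected supra-threshold
#' component containing `v` at height `h` (components under the chosen
#' connectivity, within the mask). Voxels with non-positive statistic get
#' 0; to enhance a negative contrast, negate the map first.
#'
#' @param stat 3D statistic array, or a per-mask-voxel vector.
#' @param grid the [VolumeGrid-class] (required for vector input; for an
#'   array input the mask defaults to all-true if no grid is given).
#' @param params a [TFCEParams-class].
#' @return the enhanced volume, same form as the input.
#' @examples
#' v <- array(0, c(5, 5, 5)); v[3, 3, 3] <- 1
#' tfceEnhance(v, params = tfceParams(dh = 0.001))[3, 3, 3] # ~ 1/3
#' @export
tfceEnhance <- function(stat, grid = NULL, params = tfceParams()) {
    validObject(params)
    asVector <- is.null(dim(stat))
    if (asVector) {
        if (is.null(grid)) stop("grid is required for per-mask-voxel input")
        vol <- maskToVolume(stat, grid, fill = 0)
        mask <- brainMask(grid)
    } else {
        vol <- stat
        mask <- if (is.null(grid)) array(TRUE, dim(stat)) else brainMask(grid)
    }
    if (any(!is.finite(vol[mask])))
        stop("statistic must be finite inside the mask")
    dh <- params@dh
    if (is.na(dh)) {
        mx <- max(0, vol[mask])
        dh <- max(mx / 100, 0.01)
    }
    out <- .tfceCpp(as.numeric(vol), as.logical(mask),
                    as.integer(dim(vol)), params@E, params@H, dh,
                    params@connectivity)
    out <- array(out, dim = dim(vol))
    if (asVector) out[maskIndices(grid)] else out
}

#' Voxelwise brain-behaviour correlation statistic
#'
#' At each mask voxel, regresses the per-subject map values on the demeaned
#' trait covariate and returns the slope t-statistic (a monotone transform
#' of the Pearson correlation, `t = r * sqrt((n-2) / (1-r^2))`). Voxels
#' with zero map variance — including degenerate `NaN` dissimilarity
#' voxels — get statistic 0. Perfect correlations are capped at `tCap`.
#'
#' @param maps numeric matrix, one row per in-mask voxel, one column per
#'   subject; or a [DissimilarityMaps-class] plus `contrast`.
#' @param trait numeric vector, one value per subject (column order).
#' @param demean demean the trait first (default TRUE; the statistic is
#'   invariant to it, it is kept for fidelity to the modelled design).
#' @param statistic `"t"` (default) or `"r"`.
#' @param tCap ceiling for infinite t at |r| = 1 (default 1e4).
#' @param contrast when `maps` is a [DissimilarityMaps-class], which
#'   contrast to extract.
#' @return numeric vector, one statistic per voxel (row).
#' @export
voxelwiseCorrelation <- function(maps, trait, demean = TRUE,
                                 statistic = c("t", "r"), tCap = 1e4,
                                 contrast = NULL) {
    statistic <- match.arg(statistic)
    M <- .asSubjectMatrix(maps, contrast)
    n <- ncol(M)
    if (n < 3L) stop("at least 3 subjects are required")
    if (length(trait) != n)
        stop("alignment error: trait length != number of subjects")
    if (sd(trait) == 0)
        stop("degenerate covariate: trait has zero variance")
    y <- if (demean) trait - mean(trait) else trait
    yc <- y - mean(y)
    M[!is.finite(M)] <- NA_real_
    bad <- rowSums(is.na(M)) > 0L
    M[bad, ] <- 0
    Xc <- M - rowMeans(M)
    sx <- sqrt(rowSums(Xc^2))
    r <- as.numeric(Xc %*% yc) / (sx * sqrt(sum(yc^2)))
    r[sx == 0] <- 0
    if (statistic == "r") return(r)
    r2 <- pmin(r^2, 1)
    t <- r * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
    pmin(pmax(t, -tCap), tCap)
}

# coerce DissimilarityMaps (one contrast) or matrix to voxel x subject
.asSubjectMatrix <- function(maps, contrast = NULL) {
    if (is(maps, "DissimilarityMaps")) {
        if (is.null(contrast))
            stop("specify 'contrast' for DissimilarityMaps input")
        sel <- colData(maps)$contrast == contrast
        M <- assay(maps)[, sel, drop = FALSE]
        colnames(M) <- colData(maps)$subject[sel]
        M
    } else if (is(maps, "MaskedVolumes")) {
        assay(maps)
    } else {
        as.matrix(maps)
    }
}

# all permutations of 1..n (n small), identity first
.allPerms <- function(n) {
    if (n == 1L) return(list(1L))
    sub <- .allPerms(n - 1L)
    out <- vector("list", n * length(sub))
    k <- 0L
    for (p in sub) for (pos in seq_len(n)) {
        k <- k + 1L
        out[[k]] <- append(p, n, after = pos - 1L)
    }
    # put identity first for the include-observed convention
    ids <- vapply(out, function(p) all(p == seq_len(n)), logical(1))
    c(out[ids], out[!ids])
}

#' Permutation inference with TFCE and max-statistic FWE correction
#'
#' Builds the null distribution by permuting the trait covariate across
#' subjects (Fisher-Pitman design-row shuffling): for each permutation the
#' voxelwise slope t-statistic is recomputed, TFCE-enhanced, and its
#' volume-wide maximum recorded. The FWE-corrected p-value at voxel v is
#' `(1 + #permutation maxima >= observed TFCE(v)) / (nPerm + 1)` (the
#' include-observed convention, so p is never 0), reported as the inverse
#' p-value `1 - p` where 1 is most significant. When `nPerm` is at least
#' the number of distinct permutations `n!`, the null is enumerated
#' exhaustively (with a warning) and p becomes the exact Fisher-Pitman
#' permutation p.
#'
#' @inheritParams voxelwiseCorrelation
#' @param grid the [VolumeGrid-class] the maps live on (taken from `maps`
#'   when it is a [MaskedVolumes-class]).
#' @param params a [TFCEParams-class].
#' @param nPerm number of random permutations (default 1000; the reference
#'   large-scale analysis used 30000).
#' @param seed integer RNG seed for the permutation draw.
#' @param direction `"positive"` or `"negative"`: which tail of the
#'   correlation is enhanced and tested (the negative direction enhances
#'   the negated statistic map).
#' @param label free-text tag stored in the result.
#' @return A [StatResult-class].
#' @export
permutationFWE <- function(maps, trait, grid = NULL, params = tfceParams(),
                           nPerm = 1000L, seed = 1L,
                           direction = c("positive", "negative"),
                           tCap = 1e4, contrast = NULL, label = "") {
    direction <- match.arg(direction)
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (is.null(grid) && is(maps, "MaskedVolumes")) grid <- mapGrid(maps)
    if (is.null(grid)) stop("grid is required")
    M <- .asSubjectMatrix(maps, contrast)
    n <- ncol(M)
    sgn <- if (direction == "positive") 1 else -1

    statFun <- function(y) sgn * voxelwiseCorrelation(M, y, tCap = tCap)
    obsStat <- statFun(trait)
    # fix the TFCE step across observed and permuted maps so enhanced
    # values are comparable
    dh <- params@dh
    if (is.na(dh)) dh <- max(max(0, obsStat) / 100, 0.01)
    paramsFix <- tfceParams(params@E, params@H, dh, params@connectivity)
    obsTfce <- tfceEnhance(obsStat, grid = grid, params = paramsFix)

    exhaustive <- is.finite(factorial(n)) && factorial(n) <= nPerm
    set.seed(seed)
    # draw null covariates as arrangements of the sorted trait assigned in
    # trait-rank order, so the null (and hence the p-values) is invariant
    # to consistent subject relabelling of maps and trait
    ord <- order(trait)
    base <- trait[ord]
    permCov <- function(p) {
        y <- numeric(n)
        y[ord] <- base[p]
        y
    }
    if (exhaustive) {
        warning("nPerm >= n! distinct permutations; enumerating all ",
                factorial(n), " exhaustively")
        perms <- .allPerms(n)
        maxNull <- vapply(perms, function(p) {
            max(tfceEnhance(statFun(permCov(p)), grid = grid,
                            params = paramsFix))
        }, numeric(1))
        nEff <- length(maxNull)
        # identity is among the enumerated permutations: exact p
        pvals <- vapply(obsTfce, function(v) mean(maxNull >= v - 1e-12),
                        numeric(1))
    } else {
        maxNull <- vapply(seq_len(nPerm), function(i) {
            max(tfceEnhance(statFun(permCov(sample.int(n))), grid = grid,
                            params = paramsFix))
        }, numeric(1))
        nEff <- nPerm
        pvals <- vapply(obsTfce, function(v)
            (1 + sum(maxNull >= v - 1e-12)) / (nPerm + 1), numeric(1))
    }
    new("StatResult",
        stat = obsStat, tfce = obsTfce, fweInvP = 1 - pvals, grid = grid,
        direction = direction, nPerm = as.integer(nEff),
        seed = as.integer(seed), label = as.character(label))
}

#' @rdname permutationFWE
#' @param x a `StatResult`.
#' @export
fweInvP <- function(x) x@fweInvP

#' @rdname permutationFWE
#' @export
statValues <- function(x) x@stat

#' @rdname permutationFWE
#' @export
tfceValues <- function(x) x@tfce

setMethod("show", "StatResult", function(object) {
    cat(sprintf(
        "StatResult '%s' (%s): %d perms, max 1-p = %.4f at %d voxels >= 0.95\n",
        object@label, object@direction, object@nPerm,
        max(object@fweInvP), sum(object@fweInvP >= 0.95)))
})

#' Brain-behaviour correlation battery over contrasts and subscales
#'
#' Runs [permutationFWE()] for every combination of dissimilarity contrast
#' (3), trait subscale (4) and correlation direction (2), reproducing the
#' full 24-test battery relating pattern dissimilarity to trait empathy.
#' Each test gets its own derived seed and is independently reported.
#'
#' @param dissim a [DissimilarityMaps-class] (all subjects, all contrasts).
#' @param traits data.frame with `subject_id` and subscale columns
#'   `FS`, `EC`, `PT`, `PD`; subject ids must match the maps exactly.
#' @param params a [TFCEParams-class].
#' @param nPerm permutations per test.
#' @param seed base seed; test i uses `seed + i`.
#' @param contrasts,subscales,directions optional subsets.
#' @return named list of [StatResult-class], names
#'   `<contrast>.<subscale>.<direction>`.
#' @export
runEmpathyCorrelations <- function(dissim, traits, params = tfceParams(),
                                   nPerm = 1000L, seed = 1L,
                                   contrasts = .CONTRASTS,
                                   subscales = .SUBSCALES,
                                   directions = c("positive", "negative")) {
    mapSubj <- subjectIds(dissim)
    if (!setequal(mapSubj, traits$subject_id) ||
        anyDuplicated(traits$subject_id))
        stop("alignment error: subject ids in maps and traits must match ",
             "exactly")
    traits <- traits[match(mapSubj, traits$subject_id), , drop = FALSE]
    grid <- mapGrid(dissim)
    out <- list()
    i <- 0L
    for (ct in contrasts) {
        M <- .asSubjectMatrix(dissim, ct)
        M <- M[, match(mapSubj, colnames(M)), drop = FALSE]
        for (sc in subscales) {
            if (sd(traits[[sc]]) == 0)
                stop("degenerate covariate: subscale ", sc,
                     " has zero variance")
            for (dr in directions) {
                i <- i + 1L
                nm <- paste(ct, sc, dr, sep = ".")
                out[[nm]] <- permutationFWE(
                    M, traits[[sc]], grid = grid, params = params,
                    nPerm = nPerm, seed = seed + i, direction = dr,
                    label = paste0(ct, "~", sc))
            }
        }
    }
    out
}

#' Summarise a battery of StatResults
#'
#' @param results list of [StatResult-class] (e.g. from
#'   [runEmpathyCorrelations()]).
#' @param alpha FWE significance level (default 0.05): voxels with
#'   `1 - p > 1 - alpha` count as significant.
#' @return data.frame with one row per result: label, direction, number of
#'   significant voxels, peak 1-p and the peak voxel's 0-based coordinates.
#' @export
summarizeStatResults <- function(results, alpha = 0.05) {
    rows <- lapply(names(results), function(nm) {
        r <- results[[nm]]
        ip <- r@fweInvP
        best <- which.max(ip)
        cc <- arrayInd(maskIndices(r@grid)[best], gridShape(r@grid)) - 1L
        data.frame(test = nm, label = r@label, direction = r@direction,
                   n_significant = sum(ip > 1 - alpha),
                   peak_inv_p = max(ip),
                   x = cc[1], y = cc[2], z = cc[3])
    })
    do.call(rbind, rows)
}
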