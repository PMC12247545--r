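#' Separable Gaussian smoothing of a 3D volume
#'
#' Convolves the volume with a Gaussian kernel of the given full width at
#' half maximum along each axis. Kernels are truncated at 3 standard
#' deviations and edge-renormalised so the field keeps its mean near the
#' boundary.
#'
#' @param vol 3D numeric array.
#' @param fwhm full width at half maximum in voxels; 0 returns the input.
#' @return smoothed array of the same shape.
#' @export
gaussianSmooth3D <- function(vol, fwhm) {
    if (fwhm <= 0) return(vol)
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    smooth1 <- function(d) {
        h <- max(1L, ceiling(3 * sigma))
        k <- dnorm(-h:h, sd = sigma)
        K <- matrix(0, d, d)
        for (i in seq_len(d)) {
            j <- max(1L, i - h):min(d, i + h)
            K[i, j] <- k[j - i + h + 1L]
        }
        K / rowSums(K)
    }
    dm <- dim(vol)
    # axis 1
    out <- smooth1(dm[1]) %*% matrix(vol, nrow = dm[1])
    out <- array(out, dm)
    # axis 2
    out <- aperm(out, c(2, 1, 3))
    out <- array(smooth1(dm[2]) %*% matrix(out, nrow = dm[2]),
                 dm[c(2, 1, 3)])
    out <- aperm(out, c(2, 1, 3))
    # axis 3
    out <- aperm(out, c(3, 2, 1))
    out <- array(smooth1(dm[3]) %*% matrix(out, nrow = dm[3]),
                 dm[c(3, 2, 1)])
    aperm(out, c(3, 2, 1))
}

# one smoothed, variance-rescaled Gaussian noise volume
.noiseVolume <- function(shape, fwhm, noiseSD) {
    v <- array(rnorm(prod(shape)), dim = shape)
    v <- gaussianSmooth3D(v, fwhm)
    v / sd(v) * noiseSD
}

# truncated-normal draw on [lo, hi] via inverse-CDF sampling
.rtruncnorm <- function(n, mean, sd, lo, hi) {
    if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
    u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
    qnorm(u, mean, sd)
}

#' Simulate trait questionnaire scores
#'
#' Draws the four empathy subscale sums (Fantasy FS, Empathic Concern EC,
#' Perspective Taking PT, Personal Distress PD) from truncated normal
#' distributions on the legal questionnaire range `[0, 6 * itemMax]`
#' (six items per subscale, each scored 0..`itemMax`).
#'
#' @param nSubjects number of subjects.
#' @param means,sds named numeric(4) over FS/EC/PT/PD. Defaults are typical
#'   published adult norms on the 0-30 scale.
#' @param itemMax maximum item score (default 5).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return data.frame with columns `subject_id`, `FS`, `EC`, `PT`, `PD`.
#' @examples
#' tr <- generateTraits(70, seed = 1)
#' nrow(tr)
#' @export
generateTraits <- function(nSubjects,
                           means = c(FS = 16, EC = 20, PT = 17, PD = 11),
                           sds = c(FS = 5, EC = 4, PT = 4.5, PD = 4.5),
                           itemMax = 5, seed = NULL) {
    if (any(sds < 0)) stop("sds must be >= 0")
    if (!is.null(seed)) set.seed(seed)
    hi <- 6 * itemMax
    out <- data.frame(subject_id = sprintf("sub%03d", seq_len(nSubjects)))
    for (s in .SUBSCALES)
        out[[s]] <- .rtruncnorm(nSubjects, means[[s]], sds[[s]], 0, hi)
    out
}

#' Configure a synthetic cohort
#'
#' Describes the statistical structure of a simulated multi-subject,
#' three-condition cohort of smooth z-statistic volumes. Each signal region
#' (`rois`) carries mutually orthogonal unit-norm random pattern templates,
#' one per condition; the template pair of the region's *variable contrast*
#' (default `pain_vs_control`) is rotated per subject so that its
#' noise-free normalised pattern separation is
#' `baseSep + slope * (trait - mean(trait)) + N(0, subjectSD)` (clamped to
#' (0, 2)); the remaining template pairs stay orthogonal (separation
#' sqrt(2)). Outside the regions, maps are pure spatially smoothed noise.
#'
#' @param nSubjects cohort size (default 70, three maps per subject).
#' @param grid [VolumeGrid-class]; default a 24^3 desk-scale grid with an
#'   ellipsoid mask (the full 91 x 109 x 91 grid is supported but not the
#'   default).
#' @param rois list of regions; each a list with `voxels` (linear voxel
#'   indices inside the mask), optional `name`, optional trait coupling
#'   `contrast` (default `"pain_vs_control"`), `subscale` (FS/EC/PT/PD or
#'   `NA` for none) and `slope` (separation units per trait point,
#'   default 0), and optionally fixed `templates` (an nVoxels x 3 matrix,
#'   columns pain/touch/control, overriding the generated subject-specific
#'   templates).
#' @param noiseSD noise field SD (default 1; z-statistic units).
#' @param smoothFWHM noise smoothing FWHM in voxels (default 3, matching
#'   6 mm smoothing on a 2 mm grid).
#' @param signalScale per-voxel RMS template amplitude in noise-SD units,
#'   i.e. the effective voxelwise SNR inside a region (default 1).
#' @param baseSep baseline noise-free separation of the variable contrast
#'   (default `sqrt(2)`: orthogonal templates).
#' @param subjectSD between-subject SD of the separation (default 0.1).
#' @param traitMeans,traitSDs,itemMax passed to [generateTraits()].
#' @param seed integer RNG seed (default 1).
#' @return A [SyntheticConfig-class].
#' @seealso [generateCohort()], [roiBlock()]
#' @export
syntheticConfig <- function(nSubjects = 70,
                            grid = volumeGrid(c(24, 24, 24),
                                mask = ellipsoidMask(c(24, 24, 24))),
                            rois = list(),
                            noiseSD = 1, smoothFWHM = 3, signalScale = 1,
                            baseSep = sqrt(2), subjectSD = 0.1,
                            traitMeans = c(FS = 16, EC = 20, PT = 17,
                                           PD = 11),
                            traitSDs = c(FS = 5, EC = 4, PT = 4.5,
                                         PD = 4.5),
                            itemMax = 5, seed = 1) {
    rois <- lapply(seq_along(rois), function(i) {
        roi <- rois[[i]]
        if (is.null(roi$name)) roi$name <- paste0("roi", i)
        if (is.null(roi$contrast)) roi$contrast <- "pain_vs_control"
        if (is.null(roi$slope)) roi$slope <- 0
        if (is.null(roi$subscale)) roi$subscale <- NA_character_
        roi
    })
    new("SyntheticConfig",
        nSubjects = as.integer(nSubjects), grid = grid, rois = rois,
        noiseSD = noiseSD, smoothFWHM = smoothFWHM,
        signalScale = signalScale, baseSep = baseSep,
        subjectSD = subjectSD, traitMeans = traitMeans, traitSDs = traitSDs,
        itemMax = itemMax, seed = as.integer(seed))
}

#' Cuboid region of interest inside a grid mask
#'
#' Convenience constructor of a block-shaped signal region: linear voxel
#' indices of the cuboid `[lo, hi]` (1-based, inclusive) intersected with
#' the brain mask.
#'
#' @param grid a [VolumeGrid-class].
#' @param lo,hi integer(3) corners, 1-based inclusive.
#' @return integer vector of linear voxel indices.
#' @export
roiBlock <- function(grid, lo, hi) {
    shape <- gridShape(grid)
    g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                               z = lo[3]:hi[3]))
    lin <- (g[, 3] - 1L) * (shape[1] * shape[2]) + (g[, 2] - 1L) * shape[1] +
        g[, 1]
    lin[brainMask(grid)[lin]]
}

#' Generate a synthetic cohort of condition maps and trait scores
#'
#' Simulates `nSubjects x 3` smooth z-statistic volumes following the
#' structure in [syntheticConfig()], fully reproducible from the config
#' seed. Inside each region, subject i's condition-c map adds
#' `signalScale * sqrt(nVoxels) * T_ic` (so the template's per-voxel RMS is
#' `signalScale`) to the smoothed noise field, where `T_ic` is the
#' subject's condition template; the designed noise-free separations of
#' each region's variable contrast are recorded in
#' `metadata(maps)$separations` for calibration checks.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `maps` (a [ConditionMaps-class]), `traits` (the
#'   [generateTraits()] data.frame) and `separations` (subject x region
#'   matrix of designed separations).
#' @examples
#' cfg <- syntheticConfig(nSubjects = 4, seed = 7)
#' coh <- generateCohort(cfg)
#' ncol(coh$maps) # 12 maps
#' @export
generateCohort <- function(config) {
    validObject(config)
    set.seed(config@seed)
    grid <- config@grid
    shape <- gridShape(grid)
    n <- config@nSubjects

    traits <- generateTraits(n, means = config@traitMeans,
                             sds = config@traitSDs,
                             itemMax = config@itemMax, seed = NULL)

    # per-roi orthonormal bases and per-subject separations
    nroi <- length(config@rois)
    bases <- vector("list", nroi)
    seps <- matrix(NA_real_, nrow = n, ncol = max(nroi, 1L))
    for (j in seq_len(nroi)) {
        roi <- config@rois[[j]]
        nv <- length(roi$voxels)
        bases[[j]] <- qr.Q(qr(matrix(rnorm(nv * 3L), nv, 3L)))
        z <- if (!is.na(roi$subscale)) {
            tr <- traits[[roi$subscale]]
            tr - mean(tr)
        } else rep(0, n)
        d <- config@baseSep + roi$slope * z + rnorm(n, sd = config@subjectSD)
        seps[, j] <- pmin(pmax(d, 0.05), 1.95)
    }
    if (nroi > 0)
        colnames(seps) <- vapply(config@rois, `[[`, "", "name")

    nv <- nMaskVoxels(grid)
    values <- matrix(NA_real_, nrow = nv, ncol = n * 3L)
    subj <- character(n * 3L)
    cond <- character(n * 3L)
    midx <- maskIndices(grid)
    rowOf <- integer(prod(shape))
    rowOf[midx] <- seq_along(midx)

    col <- 0L
    for (i in seq_len(n)) {
        # subject templates per roi: pair of the variable contrast rotated
        # to the designed separation, third condition orthogonal
        roiTemplates <- vector("list", nroi)
        for (j in seq_len(nroi)) {
            roi <- config@rois[[j]]
            if (!is.null(roi$templates)) {
                # user-supplied fixed per-condition templates (columns
                # pain/touch/control), subject-invariant
                roiTemplates[[j]] <- list(
                    pain = roi$templates[, 1],
                    touch = roi$templates[, 2],
                    control = roi$templates[, 3])
                next
            }
            B <- bases[[j]]
            pair <- .contrastPair(roi$contrast)
            other <- setdiff(.CONDITIONS, pair)
            d <- seps[i, j]
            # symmetric rotation: both templates of the variable pair move
            # by half the angle, so their separation is exactly d while
            # leakage of the subject effect into the other contrasts (via
            # sub-sphere cross-terms) is split and halved
            a <- acos(max(-1, min(1, 1 - d^2 / 2))) / 2
            tmpl <- list()
            tmpl[[pair[1]]] <- cos(a) * B[, 1] + sin(a) * B[, 2]
            tmpl[[pair[2]]] <- cos(a) * B[, 1] - sin(a) * B[, 2]
            tmpl[[other]] <- B[, 3]
            roiTemplates[[j]] <- tmpl
        }
        for (cn in .CONDITIONS) {
            col <- col + 1L
            vol <- .noiseVolume(shape, config@smoothFWHM, config@noiseSD)
            for (j in seq_len(nroi)) {
                roi <- config@rois[[j]]
                amp <- config@signalScale * config@noiseSD *
                    sqrt(length(roi$voxels))
                vol[roi$voxels] <- vol[roi$voxels] +
                    amp * roiTemplates[[j]][[cn]]
            }
            values[, col] <- vol[midx]
            subj[col] <- traits$subject_id[i]
            cond[col] <- cn
        }
    }

    maps <- conditionMaps(values, grid, subj, cond)
    metadata(maps)$separations <- seps
    metadata(maps)$seed <- config@seed
    list(maps = maps, traits = traits, separations = seps)
}
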