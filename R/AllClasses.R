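#' VolumeGrid: the shared voxel lattice and brain mask
#'
#' All volumes handled by the package live on a single `VolumeGrid`: a 3D
#' voxel lattice with a physical voxel size, a boolean brain mask, and an
#' affine mapping voxel indices to world (scanner) millimetre coordinates.
#' Voxel indices are 0-based in the (x, y, z) on-disk array order.
#'
#' @slot shape integer(3), voxels per axis.
#' @slot voxelSize numeric(3), voxel edge length in mm per axis.
#' @slot mask logical 3D array of the same shape; at least one `TRUE` voxel.
#' @slot affine 4x4 matrix mapping homogeneous 0-based voxel indices to mm.
#'
#' @seealso [volumeGrid()], [ellipsoidMask()], [readVolume()]
#' @export
setClass("VolumeGrid",
    representation(
        shape = "integer",
        voxelSize = "numeric",
        mask = "array",
        affine = "matrix"
    )
)

setValidity("VolumeGrid", function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 1L))
        msg <- c(msg, "shape must be 3 positive integers")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "voxelSize must be 3 positive reals")
    if (!is.logical(object@mask) || !identical(dim(object@mask),
                                               as.integer(object@shape)))
        msg <- c(msg, "mask must be a logical array of the grid shape")
    else if (!any(object@mask))
        msg <- c(msg, "mask must contain at least one TRUE voxel")
    if (!identical(dim(object@affine), c(4L, 4L)))
        msg <- c(msg, "affine must be a 4x4 matrix")
    if (length(msg)) msg else TRUE
})

#' SphereSpec: searchlight sphere geometry
#'
#' The set of integer voxel offsets within Euclidean distance
#' `radius` of the sphere centre (centre-to-centre distance in voxel
#' units, inclusive). Offsets are stored in lexicographic (dz, dy, dx)-minor
#' order, always contain (0,0,0), and are symmetric under negation.
#'
#' @slot radius non-negative sphere radius in voxels.
#' @slot offsets integer matrix, one (dx, dy, dz) row per member voxel.
#'
#' @seealso [sphereOffsets()]
#' @export
setClass("SphereSpec",
    representation(radius = "numeric", offsets = "matrix")
)

setValidity("SphereSpec", function(object) {
    r <- object@radius
    if (length(r) != 1L || is.na(r) || r < 0)
        return("radius must be a single non-negative number")
    o <- object@offsets
    if (!is.numeric(o) || ncol(o) != 3L)
        return("offsets must be an n x 3 integer matrix")
    if (any(rowSums(o^2) > r^2 + 1e-9))
        return("offsets outside the stated radius")
    if (!any(rowSums(abs(o)) == 0))
        return("offsets must contain the centre (0,0,0)")
    TRUE
})

#' MaskedVolumes: a collection of same-grid volumes as a voxel-by-sample matrix
#'
#' Base container for multi-sample volumetric data. Extends
#' `SummarizedExperiment`: the single assay holds one column per volume and
#' one row per in-mask voxel (in `maskIndices(grid)` order); the shared
#' [VolumeGrid-class] is kept in `metadata(x)$grid`.
#'
#' @seealso [ConditionMaps-class], [DissimilarityMaps-class]
#' @export
setClass("MaskedVolumes", contains = "SummarizedExperiment")

setValidity("MaskedVolumes", function(object) {
    g <- metadata(object)$grid
    if (is.null(g) || !is(g, "VolumeGrid"))
        return("metadata(x)$grid must hold a VolumeGrid")
    if (nrow(object) != sum(g@mask))
        return("assay rows must equal the number of in-mask voxels")
    TRUE
})

#' ConditionMaps: per-subject, per-condition z-statistic volumes
#'
#' A [MaskedVolumes-class] whose columns are one subject's z-statistic map
#' for one condition. `colData` carries `subject` and `condition`
#' (one of `pain`, `touch`, `control`); values must be finite inside the
#' mask.
#'
#' @seealso [conditionMaps()], [generateCohort()], [readConditionMaps()]
#' @export
setClass("ConditionMaps", contains = "MaskedVolumes")

setValidity("ConditionMaps", function(object) {
    cd <- colData(object)
    if (!all(c("subject", "condition") %in% colnames(cd)))
        return("colData must have 'subject' and 'condition'")
    if (!all(cd$condition %in% .CONDITIONS))
        return("condition must be one of pain/touch/control")
    if (anyDuplicated(paste(cd$subject, cd$condition)))
        return("duplicated (subject, condition) sample")
    if (ncol(object) > 0L && !all(is.finite(assay(object))))
        return("in-mask values must be finite")
    TRUE
})

#' DissimilarityMaps: per-subject, per-contrast pattern-distance volumes
#'
#' A [MaskedVolumes-class] whose columns hold one subject's searchlight
#' Euclidean pattern distances for one condition contrast. With unit-norm
#' pattern normalisation every value lies in [0, 2]; degenerate (all-zero
#' pattern) spheres are `NaN`.
#'
#' @seealso [dissimilaritySearchlight()]
#' @export
setClass("DissimilarityMaps", contains = "MaskedVolumes")

setValidity("DissimilarityMaps", function(object) {
    cd <- colData(object)
    if (!all(c("subject", "contrast") %in% colnames(cd)))
        return("colData must have 'subject' and 'contrast'")
    if (!all(cd$contrast %in% .CONTRASTS))
        return("contrast must be one of pain_vs_touch/pain_vs_control/touch_vs_control")
    v <- assay(object)
    if (length(v) && any(v[!is.nan(v)] < -1e-9 | v[!is.nan(v)] > 2 + 1e-9))
        return("dissimilarity values must lie in [0, 2] (or NaN)")
    TRUE
})

#' SearchlightResult: one statistic value per mask voxel
#'
#' The output of [runSearchlight()]: a statistic evaluated on the spherical
#' neighbourhood of every brain-mask voxel and written to the sphere centre.
#' Values are stored for in-mask voxels only (in `maskIndices` order);
#' [as.array()] reconstitutes the 3D volume with `NA` outside the mask.
#'
#' @slot values numeric vector, one value per in-mask voxel.
#' @slot grid the [VolumeGrid-class] the map lives on.
#' @slot statisticName label of the per-sphere statistic.
#' @slot radius searchlight radius in voxels.
#' @export
setClass("SearchlightResult",
    representation(
        values = "numeric",
        grid = "VolumeGrid",
        statisticName = "character",
        radius = "numeric"
    )
)

setValidity("SearchlightResult", function(object) {
    if (length(object@values) != sum(object@grid@mask))
        return("values length must equal the number of in-mask voxels")
    TRUE
})

#' ThresholdSpec: resel-wise Bonferroni + exact binomial accuracy threshold
#'
#' Bundles the significance machinery for a cross-participant accuracy map:
#' the nominal alpha, the resel count (number of non-overlapping searchlight
#' spheres fitting in the brain mask), the Bonferroni-corrected alpha, and
#' the critical number of correct classifications under the exact binomial
#' null at chance level.
#'
#' @slot alphaNominal nominal family-wise alpha (default 0.05).
#' @slot reselCount effective number of independent tests.
#' @slot alphaCorrected `alphaNominal / reselCount`.
#' @slot nClassifications binomial n (subjects x conditions).
#' @slot chanceP chance success probability (1/3 for three conditions).
#' @slot kCritical critical correct-classification count.
#' @slot accuracyCritical `kCritical / nClassifications`.
#' @slot attainable FALSE when no k <= n meets the corrected alpha.
#' @slot convention `"invcdf"` or `"tail"`; see [binomialThreshold()].
#' @export
setClass("ThresholdSpec",
    representation(
        alphaNominal = "numeric",
        reselCount = "integer",
        alphaCorrected = "numeric",
        nClassifications = "integer",
        chanceP = "numeric",
        kCritical = "integer",
        accuracyCritical = "numeric",
        attainable = "logical",
        convention = "character"
    )
)

#' TFCEParams: threshold-free cluster enhancement parameters
#'
#' @slot E extent exponent (default 0.5, the standard value for 3D volumes).
#' @slot H height exponent (default 2.0).
#' @slot dh integration step in statistic units; `NA` selects an adaptive
#'   step of (max statistic)/100 with a floor of 0.01.
#' @slot connectivity 6, 18 or 26 (default 26) neighbourhood for connected
#'   components.
#' @seealso [tfceParams()], [tfceEnhance()]
#' @export
setClass("TFCEParams",
    representation(
        E = "numeric", H = "numeric", dh = "numeric",
        connectivity = "integer"
    )
)

setValidity("TFCEParams", function(object) {
    msg <- character()
    if (object@E < 0 || object@H < 0) msg <- c(msg, "E and H must be >= 0")
    if (!is.na(object@dh) && object@dh <= 0) msg <- c(msg, "dh must be > 0")
    if (!object@connectivity %in% c(6L, 18L, 26L))
        msg <- c(msg, "connectivity must be 6, 18 or 26")
    if (length(msg)) msg else TRUE
})

#' StatResult: permutation inference output for one brain-behaviour test
#'
#' Holds, per in-mask voxel: the observed voxelwise statistic (slope
#' t-statistic of map values on the demeaned trait), its TFCE enhancement,
#' and the family-wise-error corrected inverse p-value (1 - p, where 1 is
#' most significant) from the max-statistic permutation null.
#'
#' @slot stat observed voxelwise t statistic (sign follows `direction`).
#' @slot tfce TFCE-enhanced statistic.
#' @slot fweInvP FWE-corrected 1 - p per voxel, in [0, 1].
#' @slot grid the [VolumeGrid-class].
#' @slot direction `"positive"` or `"negative"` correlation contrast.
#' @slot nPerm number of permutations used (or the exhaustive count).
#' @slot seed RNG seed of the permutation draw.
#' @slot label free-text tag, e.g. `"pain_vs_control~EC"`.
#' @seealso [permutationFWE()], [runEmpathyCorrelations()]
#' @export
setClass("StatResult",
    representation(
        stat = "numeric",
        tfce = "numeric",
        fweInvP = "numeric",
        grid = "VolumeGrid",
        direction = "character",
        nPerm = "integer",
        seed = "integer",
        label = "character"
    )
)

setValidity("StatResult", function(object) {
    nv <- sum(object@grid@mask)
    if (length(object@stat) != nv || length(object@tfce) != nv ||
        length(object@fweInvP) != nv)
        return("stat/tfce/fweInvP must have one value per in-mask voxel")
    p <- object@fweInvP
    if (any(p < 0 | p > 1, na.rm = TRUE))
        return("fweInvP must lie in [0, 1]")
    if (!object@direction %in% c("positive", "negative"))
        return("direction must be 'positive' or 'negative'")
    TRUE
})

#' SyntheticConfig: full description of a simulated cohort
#'
#' Encodes the study conditions a synthetic cohort emulates: cohort size,
#' grid, seeded signal regions with per-condition pattern templates, noise
#' level and spatial smoothness, per-region trait coupling of pattern
#' separation, and the RNG seed. See [syntheticConfig()] for field
#' semantics and defaults.
#'
#' @slot nSubjects number of subjects (3 condition maps each).
#' @slot grid the [VolumeGrid-class] maps are simulated on.
#' @slot rois list of signal regions: each a list with `name`, `voxels`
#'   (linear voxel indices), and optionally `contrast`, `subscale`, `slope`.
#' @slot noiseSD standard deviation of the smoothed noise field.
#' @slot smoothFWHM Gaussian smoothing FWHM of the noise, in voxels.
#' @slot signalScale per-voxel RMS amplitude of the region templates, in
#'   noise-SD units (an effective voxelwise SNR).
#' @slot baseSep baseline noise-free pattern separation between the two
#'   conditions of each region's variable contrast (default sqrt(2),
#'   i.e. orthogonal unit templates).
#' @slot subjectSD between-subject SD of the pattern separation.
#' @slot traitMeans,traitSDs named numeric(4) over FS/EC/PT/PD.
#' @slot itemMax maximum item score; subscales live in [0, 6*itemMax].
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig",
    representation(
        nSubjects = "integer",
        grid = "VolumeGrid",
        rois = "list",
        noiseSD = "numeric",
        smoothFWHM = "numeric",
        signalScale = "numeric",
        baseSep = "numeric",
        subjectSD = "numeric",
        traitMeans = "numeric",
        traitSDs = "numeric",
        itemMax = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
    if (object@noiseSD <= 0) msg <- c(msg, "noiseSD must be > 0")
    if (object@smoothFWHM < 0) msg <- c(msg, "smoothFWHM must be >= 0")
    if (object@subjectSD < 0) msg <- c(msg, "subjectSD must be >= 0")
    nmask <- which(object@grid@mask)
    for (roi in object@rois) {
        if (is.null(roi$voxels) || length(roi$voxels) < 3L) {
            msg <- c(msg, "each roi needs >= 3 voxels")
        } else if (!all(roi$voxels %in% nmask)) {
            msg <- c(msg, sprintf("roi '%s' has voxels outside the mask",
                                  if (is.null(roi$name)) "?" else roi$name))
        }
        if (!is.null(roi$contrast) && !roi$contrast %in% .CONTRASTS)
            msg <- c(msg, "roi contrast must be a valid contrast name")
        if (!is.null(roi$subscale) && !is.na(roi$subscale) &&
            !roi$subscale %in% .SUBSCALES)
            msg <- c(msg, "roi subscale must be one of FS/EC/PT/PD")
        if (!is.null(roi$templates) &&
            (!is.matrix(roi$templates) ||
             nrow(roi$templates) != length(roi$voxels) ||
             ncol(roi$templates) != 3L))
            msg <- c(msg, "roi templates must be an nVoxels x 3 matrix")
    }
    if (length(msg)) msg else TRUE
})
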