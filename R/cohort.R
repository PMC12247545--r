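#' Build a ConditionMaps container
#'
#' @param values numeric matrix with one row per in-mask voxel (in
#'   [maskIndices()] order) and one column per sample, or a list of 3D
#'   arrays on `grid`.
#' @param grid the shared [VolumeGrid-class].
#' @param subject character vector, one subject id per sample.
#' @param condition character vector over `pain`/`touch`/`control`.
#' @return A [ConditionMaps-class].
#' @export
conditionMaps <- function(values, grid, subject, condition) {
    if (is.list(values))
        values <- vapply(values, volumeToMask, numeric(nMaskVoxels(grid)),
                         grid = grid)
    colnames(values) <- paste(subject, condition, sep = "_")
    se <- SummarizedExperiment(
        assays = list(zstat = values),
        colData = DataFrame(subject = as.character(subject),
                            condition = as.character(condition)),
        metadata = list(grid = grid)
    )
    new("ConditionMaps", se)
}

#' @rdname conditionMaps
#' @param x a [MaskedVolumes-class].
#' @export
mapGrid <- function(x) metadata(x)$grid

#' @rdname conditionMaps
#' @export
subjectIds <- function(x) unique(as.character(colData(x)$subject))

setMethod("show", "ConditionMaps", function(object) {
    cat(sprintf("ConditionMaps: %d subjects x %d conditions, %d mask voxels\n",
                length(subjectIds(object)),
                length(unique(colData(object)$condition)), nrow(object)))
})

setMethod("show", "DissimilarityMaps", function(object) {
    cat(sprintf(
        "DissimilarityMaps: %d subjects x %d contrasts, %d mask voxels\n",
        length(subjectIds(object)),
        length(unique(colData(object)$contrast)), nrow(object)))
})

# check every subject has exactly one map per condition; returns subjects
.checkCompleteCohort <- function(x, minSubjects = 1L) {
    cd <- colData(x)
    tab <- table(cd$subject, factor(cd$condition, levels = .CONDITIONS))
    if (nrow(tab) < minSubjects)
        stop("dataset error: at least ", minSubjects,
             " subjects are required")
    if (any(tab != 1L)) {
        bad <- rownames(tab)[rowSums(tab != 1L) > 0][1]
        stop("dataset error: subject '", bad,
             "' does not have exactly one map per condition")
    }
    rownames(tab)
}

#' Read a cohort of per-subject condition volumes from disk
#'
#' Expects one single-volume NIfTI file per subject and condition named
#' `<subject>_<condition>.nii.gz` (or `.nii`) under `dir`.
#'
#' @param dir directory containing the volumes.
#' @param subjects character vector of subject ids.
#' @param grid the target [VolumeGrid-class] (e.g. from [readMask()]).
#' @param conditions condition names (default all three).
#' @return A [ConditionMaps-class].
#' @export
readConditionMaps <- function(dir, subjects, grid,
                              conditions = c("pain", "touch", "control")) {
    nv <- nMaskVoxels(grid)
    n <- length(subjects) * length(conditions)
    values <- matrix(NA_real_, nrow = nv, ncol = n)
    subj <- character(n)
    cond <- character(n)
    i <- 0L
    for (s in subjects) {
        for (cn in conditions) {
            i <- i + 1L
            f <- file.path(dir, paste0(s, "_", cn, ".nii.gz"))
            if (!file.exists(f))
                f <- file.path(dir, paste0(s, "_", cn, ".nii"))
            if (!file.exists(f))
                stop("alignment error: missing volume for subject '", s,
                     "', condition '", cn, "' in ", dir)
            v <- readVolume(f, grid = grid)
            values[, i] <- volumeToMask(v$values, grid)
            subj[i] <- s
            cond[i] <- cn
        }
    }
    conditionMaps(values, grid, subj, cond)
}

#' Write a cohort of condition volumes to disk
#'
#' Inverse of [readConditionMaps()]: one `<subject>_<condition>.nii.gz`
#' per column.
#'
#' @param x a [ConditionMaps-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeConditionMaps <- function(x, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    grid <- mapGrid(x)
    cd <- colData(x)
    paths <- character(ncol(x))
    for (i in seq_len(ncol(x))) {
        paths[i] <- file.path(dir, paste0(cd$subject[i], "_",
                                          cd$condition[i], ".nii.gz"))
        writeVolume(assay(x)[, i], paths[i], grid = grid)
    }
    invisible(paths)
}
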