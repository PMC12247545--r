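#' Run a statistic-agnostic spherical searchlight
#'
#' Evaluates `statistic` on the clipped spherical neighbourhood of every
#' brain-mask voxel (or a chosen subset of centres) and writes the result
#' to the sphere centre. The engine is shared by the decoding and the
#' dissimilarity searchlights: the per-sphere statistic receives the
#' voxel-by-sample pattern matrix for one sphere (rows = member voxels in
#' offset order, columns = the input volumes) and must return one real.
#' Traversal is deterministic, so results do not depend on evaluation
#' order.
#'
#' @param x a [MaskedVolumes-class] (all volumes on one grid).
#' @param statistic `function(patterns)` returning a single numeric; it may
#'   also accept the sample annotation via a second argument, in which case
#'   `colData(x)` is passed.
#' @param sphere a [SphereSpec-class] (default radius 3).
#' @param centers optional integer vector of mask-voxel indices (positions
#'   in [maskIndices()] order) to evaluate; default all. Unevaluated
#'   centres are `NA`.
#' @param statisticName label stored in the result.
#' @return A [SearchlightResult-class].
#' @examples
#' g <- volumeGrid(c(8, 8, 8))
#' m <- conditionMaps(matrix(1.5, 512, 3), g, rep("s1", 3),
#'                    c("pain", "touch", "control"))
#' r <- runSearchlight(m, function(p) mean(p), sphereOffsets(1))
#' @export
runSearchlight <- function(x, statistic, sphere = sphereOffsets(3),
                           centers = NULL, statisticName = "statistic") {
    grid <- mapGrid(x)
    Z <- assay(x)
    nbr <- .sphereRowIndex(grid, sphere)
    nC <- nrow(nbr)
    if (is.null(centers)) centers <- seq_len(nC)
    passMeta <- length(formals(statistic)) >= 2L
    cd <- colData(x)
    values <- rep(NA_real_, nC)
    for (ci in centers) {
        rows <- nbr[ci, ]
        rows <- rows[rows > 0L]
        values[ci] <- tryCatch({
            P <- Z[rows, , drop = FALSE]
            if (passMeta) statistic(P, cd) else statistic(P)
        }, error = function(e) {
            cc <- arrayInd(maskIndices(grid)[ci], gridShape(grid)) - 1L
            stop("searchlight statistic failed at centre (",
                 paste(cc, collapse = ", "), "): ", conditionMessage(e),
                 call. = FALSE)
        })
    }
    new("SearchlightResult", values = values, grid = grid,
        statisticName = statisticName, radius = sphereRadius(sphere))
}

#' @rdname runSearchlight
#' @param result a `SearchlightResult`.
#' @export
slValues <- function(result) result@values

setMethod("show", "SearchlightResult", function(object) {
    v <- object@values[!is.na(object@values)]
    cat(sprintf(
        "SearchlightResult '%s' (radius %g): %d/%d centres, range [%g, %g]\n",
        object@statisticName, object@radius, length(v),
        length(object@values),
        if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

#' Convert a SearchlightResult to a full 3D array
#'
#' @param x a [SearchlightResult-class].
#' @param ... ignored.
#' @return 3D array with `NA` outside the mask.
#' @export
setMethod("as.array", "SearchlightResult", function(x, ...) {
    maskToVolume(x@values, x@grid)
})
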