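#' Enumerate searchlight sphere offsets
#'
#' Returns all integer voxel offsets (dx, dy, dz) with
#' `dx^2 + dy^2 + dz^2 <= radius^2` (centre-to-centre Euclidean distance in
#' voxel units, inclusive), in deterministic lexicographic order. The
#' default radius of 3 voxels gives the 123-voxel approximately spherical
#' neighbourhood used throughout the pipeline.
#'
#' @param radius non-negative sphere radius in voxels.
#' @return A [SphereSpec-class].
#' @examples
#' nrow(sphereOffsets(3)@offsets) # 123
#' @export
sphereOffsets <- function(radius = 3) {
    if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
        radius < 0)
        stop("invalid parameter: radius must be a single non-negative number")
    r <- floor(radius)
    g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
    g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
    # lexicographic (dx, dy, dz)
    g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
    storage.mode(g) <- "integer"
    rownames(g) <- NULL
    new("SphereSpec", radius = radius, offsets = g)
}

#' @rdname sphereOffsets
#' @param x a `SphereSpec`.
#' @export
sphereRadius <- function(x) x@radius

#' @rdname sphereOffsets
#' @export
nSphereVoxels <- function(x) nrow(x@offsets)

setMethod("show", "SphereSpec", function(object) {
    cat(sprintf("SphereSpec: radius %g voxels, %d offsets\n",
                object@radius, nrow(object@offsets)))
})

# Per-centre assay-row indices for every in-mask voxel.
# Returns an integer matrix nCentres x nOffsets with 0 marking neighbours
# that fall outside the grid or outside the mask; row i corresponds to the
# i-th mask voxel in maskIndices() order. Sphere membership is clipped at
# mask/grid edges (out-of-mask voxels dropped), so every mask voxel keeps a
# (possibly shorter) pattern.
.sphereRowIndex <- function(grid, sphere) {
    shape <- gridShape(grid)
    midx <- maskIndices(grid)
    rowOf <- integer(prod(shape))
    rowOf[midx] <- seq_along(midx)
    cc <- arrayInd(midx, shape)
    off <- sphere@offsets
    out <- matrix(0L, nrow = length(midx), ncol = nrow(off))
    for (k in seq_len(nrow(off))) {
        x <- cc[, 1] + off[k, 1]
        y <- cc[, 2] + off[k, 2]
        z <- cc[, 3] + off[k, 3]
        ok <- x >= 1L & x <= shape[1] & y >= 1L & y <= shape[2] &
            z >= 1L & z <= shape[3]
        lin <- (z[ok] - 1L) * (shape[1] * shape[2]) +
            (y[ok] - 1L) * shape[1] + x[ok]
        out[ok, k] <- rowOf[lin]
    }
    out
}

#' Extract the sphere pattern vector at a voxel
#'
#' Values of one volume at the sphere member voxels around `centre` that
#' fall inside the grid bounds and inside the brain mask, in sphere offset
#' order. For a fixed centre the member set is identical across all volumes
#' on the same grid, so patterns from different maps align element-wise.
#'
#' @param map 3D array on `grid` (or per-mask-voxel vector).
#' @param centre voxel index triple, 0-based (on-disk array order).
#' @param sphere a [SphereSpec-class].
#' @param grid the [VolumeGrid-class].
#' @return numeric pattern vector (length <= number of sphere offsets).
#' @export
extractPattern <- function(map, centre, sphere, grid) {
    shape <- gridShape(grid)
    c1 <- as.integer(centre) + 1L # to 1-based
    if (any(c1 < 1L) || any(c1 > shape))
        stop("invalid centre: outside the grid")
    lin <- (c1[3] - 1L) * (shape[1] * shape[2]) + (c1[2] - 1L) * shape[1] +
        c1[1]
    if (!brainMask(grid)[lin])
        stop("invalid centre: voxel is outside the brain mask")
    if (is.null(dim(map))) map <- maskToVolume(map, grid)
    off <- sphere@offsets
    x <- c1[1] + off[, 1]
    y <- c1[2] + off[, 2]
    z <- c1[3] + off[, 3]
    ok <- x >= 1L & x <= shape[1] & y >= 1L & y <= shape[2] &
        z >= 1L & z <= shape[3]
    linN <- (z[ok] - 1L) * (shape[1] * shape[2]) + (y[ok] - 1L) * shape[1] +
        x[ok]
    inMask <- brainMask(grid)[linN]
    map[linN[inMask]]
}
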