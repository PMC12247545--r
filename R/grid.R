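#' Construct a VolumeGrid
#'
#' @param shape integer(3): voxels per axis.
#' @param voxelSize numeric(3): voxel edge lengths in mm (default 2 mm
#'   isotropic, the resolution of the standard 91 x 109 x 91 MNI grid).
#' @param mask logical 3D array of the same shape; `NULL` means all-true.
#' @param affine optional 4x4 voxel-to-mm matrix; default is a diagonal
#'   scaling by `voxelSize`.
#' @return A [VolumeGrid-class].
#' @examples
#' g <- volumeGrid(c(24, 24, 24), mask = ellipsoidMask(c(24, 24, 24)))
#' nMaskVoxels(g)
#' @export
volumeGrid <- function(shape, voxelSize = c(2, 2, 2), mask = NULL,
                       affine = NULL) {
    shape <- as.integer(shape)
    if (is.null(mask)) mask <- array(TRUE, dim = shape)
    if (is.null(affine)) {
        affine <- diag(c(voxelSize, 1))
    }
    new("VolumeGrid", shape = shape, voxelSize = as.numeric(voxelSize),
        mask = mask, affine = affine)
}

#' Ellipsoid brain mask
#'
#' A synthetic smooth convex "brain" used as the default test mask, so no
#' atlas download is needed. Voxels inside the ellipsoid
#' `sum(((i - centre) / semiAxes)^2) <= 1` are in-mask.
#'
#' @param shape integer(3) grid shape.
#' @param centre ellipsoid centre in 1-based voxel coordinates
#'   (default grid centre).
#' @param semiAxes ellipsoid semi-axes in voxels (default 40% of shape).
#' @return logical 3D array.
#' @export
ellipsoidMask <- function(shape, centre = (shape + 1) / 2,
                          semiAxes = 0.4 * shape) {
    shape <- as.integer(shape)
    ix <- (seq_len(shape[1]) - centre[1]) / semiAxes[1]
    iy <- (seq_len(shape[2]) - centre[2]) / semiAxes[2]
    iz <- (seq_len(shape[3]) - centre[3]) / semiAxes[3]
    d2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
    array(d2 <= 1, dim = shape)
}

#' @rdname volumeGrid
#' @param x,object a `VolumeGrid`.
#' @export
gridShape <- function(x) x@shape

#' @rdname volumeGrid
#' @export
voxelSize <- function(x) x@voxelSize

#' @rdname volumeGrid
#' @export
brainMask <- function(x) x@mask

#' @rdname volumeGrid
#' @export
gridAffine <- function(x) x@affine

#' Linear indices of in-mask voxels, in array (column-major) order
#' @rdname volumeGrid
#' @export
maskIndices <- function(x) which(x@mask)

#' @rdname volumeGrid
#' @export
nMaskVoxels <- function(x) sum(x@mask)

setMethod("show", "VolumeGrid", function(object) {
    cat(sprintf(
        "VolumeGrid %s, voxel %s mm, %d/%d voxels in mask\n",
        paste(object@shape, collapse = " x "),
        paste(format(object@voxelSize), collapse = " x "),
        sum(object@mask), prod(object@shape)
    ))
})

# check that two grids are compatible (same lattice and mask)
.checkSameGrid <- function(a, b) {
    if (!identical(a@shape, b@shape) || !identical(a@mask, b@mask))
        stop("grid mismatch: volumes do not share the same lattice and mask")
    invisible(TRUE)
}

#' Embed per-mask-voxel values into a full 3D volume
#'
#' @param values numeric vector with one entry per in-mask voxel (in
#'   [maskIndices()] order).
#' @param grid the [VolumeGrid-class].
#' @param fill value outside the mask (default `NA`).
#' @return 3D array of the grid shape.
#' @export
maskToVolume <- function(values, grid, fill = NA_real_) {
    stopifnot(length(values) == nMaskVoxels(grid))
    vol <- array(fill, dim = gridShape(grid))
    vol[maskIndices(grid)] <- values
    vol
}

#' Extract in-mask values from a full 3D volume
#'
#' @param vol 3D array of the grid shape.
#' @inheritParams maskToVolume
#' @return numeric vector in [maskIndices()] order.
#' @export
volumeToMask <- function(vol, grid) {
    if (!identical(dim(vol), as.integer(gridShape(grid))))
        stop("grid mismatch: volume shape ",
             paste(dim(vol), collapse = "x"), " != grid shape ",
             paste(gridShape(grid), collapse = "x"))
    vol[maskIndices(grid)]
}
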