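#' Read and write single-volume NIfTI images
#'
#' Thin wrappers around RNifti that bind volumes to a [VolumeGrid-class].
#' `readVolume()` reads a single 3D NIfTI-1/2 volume (optionally gzipped)
#' and returns the value array plus grid metadata; `readMask()` reads a
#' 0/1 volume as a logical mask; `writeVolume()` writes an array, a
#' [SearchlightResult-class], or per-mask-voxel values to disk. A write
#' followed by a read round-trips values bit-exactly (data are written in
#' 64-bit float).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param grid optional already-bound [VolumeGrid-class]; a shape mismatch
#'   with the file is an error.
#' @return `readVolume()`: a list with `values` (3D array) and `grid`;
#'   `readMask()`: a [VolumeGrid-class] whose mask is the file's nonzero
#'   voxels.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' g <- volumeGrid(c(8, 8, 8))
#' writeVolume(array(rnorm(512), c(8, 8, 8)), f, g)
#' v <- readVolume(f)
#' dim(v$values)
#' @export
readVolume <- function(path, grid = NULL) {
    img <- RNifti::readNifti(path)
    values <- as.array(img)
    if (length(dim(values)) == 4L && dim(values)[4] == 1L)
        values <- array(values, dim = dim(values)[1:3])
    if (length(dim(values)) != 3L)
        stop("expected a single 3D volume in ", path)
    values <- array(as.numeric(values), dim = dim(values)[1:3])
    pix <- attr(img, "pixdim")
    if (is.null(pix)) pix <- c(1, 1, 1)
    vs <- abs(as.numeric(pix[1:3]))
    aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
    fileGrid <- volumeGrid(dim(values), voxelSize = vs, affine = aff)
    if (!is.null(grid)) {
        if (!identical(gridShape(grid), gridShape(fileGrid)))
            stop("grid mismatch: ", path, " has shape ",
                 paste(gridShape(fileGrid), collapse = "x"),
                 " but the bound grid is ",
                 paste(gridShape(grid), collapse = "x"))
        fileGrid <- grid
    }
    list(values = values, grid = fileGrid)
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
    v <- readVolume(path)
    mask <- array(v$values != 0, dim = dim(v$values))
    volumeGrid(gridShape(v$grid), voxelSize = voxelSize(v$grid),
               mask = mask, affine = gridAffine(v$grid))
}

#' @rdname readVolume
#' @param x 3D array, per-mask-voxel numeric vector, or
#'   [SearchlightResult-class].
#' @param datatype NIfTI storage type (default `"double"` for bit-exact
#'   round trips).
#' @export
writeVolume <- function(x, path, grid = NULL, datatype = "double") {
    if (is(x, "SearchlightResult")) {
        grid <- x@grid
        x <- maskToVolume(x@values, grid)
    } else if (is.null(dim(x))) {
        if (is.null(grid)) stop("grid is required for per-mask-voxel values")
        x <- maskToVolume(as.numeric(x), grid)
    }
    if (!is.null(grid)) {
        if (!identical(dim(x), as.integer(gridShape(grid))))
            stop("grid mismatch: array shape does not match the bound grid")
        img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)))
        img <- RNifti::`pixdim<-`(img, voxelSize(grid))
    } else {
        img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)))
    }
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

# JSON sidecar describing how a result volume was produced
.writeSidecar <- function(path, grid, extra = list()) {
    meta <- c(list(
        package = "SearchlightMVPA",
        version = as.character(packageVersion("SearchlightMVPA")),
        grid_shape = gridShape(grid),
        mask_voxels = nMaskVoxels(grid),
        mask_checksum = sum(which(brainMask(grid)))
    ), extra)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(meta)
}
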