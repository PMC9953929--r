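#' A 3D scalar volume with physical voxel size
#'
#' `vol3d()` wraps a numeric 3D array together with its voxel size in
#' millimetres and an integer origin offset recording where the grid sits
#' inside any parent grid it was cropped from. It is the unit every stage of
#' the pipeline consumes and produces: the synthetic cohort generator writes
#' them, the preprocessing tail crops and smooths them, and patch extraction
#' slices them.
#'
#' @param data a numeric 3D array with all extents >= 1 and no missing or
#'   non-finite values.
#' @param voxel_size_mm voxel edge length in mm; a single positive number
#'   (isotropic) or one per axis.
#' @param origin_offset integer triple; the 0-based start of this grid within
#'   the grid it was cropped from. `c(0, 0, 0)` for an uncropped volume.
#'
#' @return An object of class `vol3d`.
#' @seealso [read_volume()], [write_volume()], [crop_bounding_box()],
#'   [smooth_gaussian()]
#' @export
#' @examples
#' v <- vol3d(array(runif(8 * 10 * 8), c(8, 10, 8)), voxel_size_mm = 1.5)
#' dim(v)
vol3d <- function(data, voxel_size_mm = 1.5, origin_offset = c(0L, 0L, 0L)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (anyNA(data) || !all(is.finite(data))) {
    stop("`data` must not contain missing or non-finite values", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all extents must be >= 1", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be positive (length 1 or 3)", call. = FALSE)
  }
  origin_offset <- as.integer(origin_offset)
  if (length(origin_offset) != 3L || anyNA(origin_offset)) {
    stop("`origin_offset` must be an integer triple", call. = FALSE)
  }
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         origin_offset = origin_offset),
    class = "vol3d"
  )
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' @export
as.array.vol3d <- function(x, ...) x$data

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<vol3d> %d x %d x %d voxels @ %s mm, offset (%s)\n",
    d[1], d[2], d[3],
    paste(format(x$voxel_size_mm, trim = TRUE), collapse = " x "),
    paste(x$origin_offset, collapse = ", ")
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a NIfTI-1 volume from disk
#'
#' Reads a `.nii` or `.nii.gz` file and returns a [vol3d], taking the voxel
#' size from the header `pixdim`.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [vol3d].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim(arr)[1:3])
  }
  vs <- RNifti::pixdim(img)[1:3]
  vol3d(arr, voxel_size_mm = vs)
}

#' Write a volume to a NIfTI-1 file
#'
#' The voxel size is recorded in the header `pixdim`. The directory is
#' created if needed.
#'
#' @param v a [vol3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "vol3d"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# internal: coerce array-or-vol3d to vol3d (arrays get default voxel size)
as_vol3d <- function(x, voxel_size_mm = 1.5) {
  if (inherits(x, "vol3d")) x else vol3d(x, voxel_size_mm = voxel_size_mm)
}
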