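#' @useDynLib subcortnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a volume grid
#'
#' A `volume_grid` is the carrier for every 3D scalar field in the pipeline:
#' correlation maps, statistical maps, streamline density maps and integer
#' label volumes. It couples a 3D array with a 4x4 voxel-to-world affine
#' (0-based voxel indices, voxel-centre convention).
#'
#' @param data 3D numeric or integer array.
#' @param affine 4x4 invertible voxel-to-world transform (mm).
#' @param meta optional named list of free-form metadata.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, affine, meta = list()) {
  if (length(dim(data)) != 3L)
    stop("volume_grid expects a 3D array, got ", length(dim(data)), " dimensions")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine is not invertible")
  structure(list(data = data, affine = affine, meta = meta), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ", paste(signif(voxel_size(x), 3), collapse = " x "),
      " mm, ", storage.mode(x$data), "\n", sep = "")
  invisible(x)
}

#' Voxel dimensions (mm) of a volume grid
#' @param vol a `volume_grid`
#' @return numeric length-3 vector of voxel edge lengths in mm.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Test two grids for identical geometry
#' @param a,b `volume_grid` objects
#' @param tol absolute tolerance on affine entries.
#' @return logical
#' @export
same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) && all(abs(a$affine - b$affine) < tol)
}

stop_unless_same_geometry <- function(maps, what = "maps") {
  ref <- maps[[1]]
  bad <- which(!vapply(maps, same_geometry, logical(1), b = ref))
  if (length(bad))
    stop("geometry mismatch in ", what, " at positions: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Map 0-based voxel indices to world mm coordinates
#' @param affine 4x4 voxel-to-world transform.
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

#' Map world mm coordinates to 0-based voxel indices
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param ndim expected dimensionality, 3 or 4.
#' @return a `volume_grid` (3D) or `bold_series` (4D).
#' @export
read_volume <- function(path, ndim = 3L) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != ndim)
    stop("expected a ", ndim, "D volume but '", path, "' has ",
         length(dim(arr)), " dimensions")
  affine <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  attributes(affine) <- list(dim = dim(affine))
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("non-invertible affine in '", path, "'")
  if (ndim == 3L) volume_grid(arr, affine, meta = list(path = path))
  else bold_series(arr, affine, meta = list(path = path))
}

#' Write a volume to NIfTI-1
#'
#' Integer arrays are written as int32 (bit-exact round trip); numeric arrays
#' as float32.
#'
#' @param vol a `volume_grid` or `bold_series`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- vol$data
  dtype <- if (is.integer(arr)) "int32" else "float"
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Construct a BOLD time-series volume
#'
#' A 4D array (x, y, z, t) sharing the geometry conventions of
#' [volume_grid()].
#'
#' @param data 4D numeric array.
#' @param affine 4x4 voxel-to-world transform.
#' @param meta optional metadata list.
#' @return object of class `bold_series`.
#' @export
bold_series <- function(data, affine, meta = list()) {
  if (length(dim(data)) != 4L)
    stop("bold_series expects a 4D array")
  affine <- unname(as.matrix(affine))
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine is not invertible")
  structure(list(data = data, affine = affine, meta = meta), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_series> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " timepoints\n", sep = "")
  invisible(x)
}

#' Number of timepoints of a BOLD series
#' @param bold a `bold_series`
#' @return integer count.
#' @export
n_timepoints <- function(bold) dim(bold$data)[4]

# Internal: matrix view (voxels x time) without copy semantics surprises.
bold_matrix <- function(bold) {
  d <- dim(bold$data)
  matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
}
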