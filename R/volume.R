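#' Image volumes
#'
#' An `image_volume` is a 3D scalar grid together with the mapping from voxel
#' indices to world coordinates in millimetres. The convention, used
#' throughout the package, is RAS-like axes with the affine equal to
#' `diag(spacing)` plus an origin at the volume corner: the centre of the
#' voxel with (0-based) index `i` sits at `i * spacing + origin` mm. In R the
#' array is 1-based, so the centre of `data[i, j, k]` is at
#' `(c(i, j, k) - 1) * spacing + origin`.
#'
#' @param data numeric 3D array of voxel values.
#' @param spacing isotropic or per-axis voxel spacing in mm (length 1 or 3);
#'   the imaging protocol emulated here uses isotropic 0.65 mm voxels.
#' @param origin world coordinate (mm) of the centre of the first voxel.
#'
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `spacing` and `origin`.
#' @examples
#' vol <- image_volume(array(0, c(8, 8, 8)), spacing = 0.65)
#' dim(vol)
#' voxel_volume(vol) # 0.65^3 mm^3
#' @export
image_volume <- function(data, spacing = 0.65, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive voxel sizes in mm.")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be a finite length-3 world coordinate in mm.")
  }
  structure(
    list(data = data, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
as.array.image_volume <- function(x, ...) x$data

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
    d[1], d[2], d[3],
    paste(signif(x$spacing, 4), collapse = " x "),
    paste(signif(x$origin, 4), collapse = ", ")
  ))
  cat(sprintf(
    "  intensity range [%.4g, %.4g]\n",
    min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)
  ))
  invisible(x)
}

#' @rdname image_volume
#' @param x an `image_volume`.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' World coordinates of all voxel centres
#'
#' @param x an `image_volume`.
#' @return An n-by-3 matrix of mm coordinates, voxels in array (column-major)
#'   order.
#' @keywords internal
voxel_centers <- function(x) {
  d <- dim(x$data)
  idx <- arrayInd(seq_len(prod(d)), d)
  sweep(sweep(idx - 1, 2, x$spacing, "*"), 2, x$origin, "+")
}

#' Convert world mm coordinates to continuous (1-based) voxel indices
#' @keywords internal
world_to_index <- function(x, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, x$origin, "-"), 2, x$spacing, "/") + 1
}

#' Bounding check: are continuous indices inside the grid?
#' @keywords internal
index_in_grid <- function(ci, d, tol = 0) {
  ci[, 1] >= 1 - tol & ci[, 1] <= d[1] + tol &
    ci[, 2] >= 1 - tol & ci[, 2] <= d[2] + tol &
    ci[, 3] >= 1 - tol & ci[, 3] <= d[3] + tol
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' translate to and from the package's `image_volume` container. Only the
#' diagonal part of the NIfTI affine (spacing and corner origin) is
#' represented; oblique orientations are not supported.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an `image_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::niftiHeader(img)$pixdim[2:4]
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) abort("only 3D NIfTI volumes are supported.")
  image_volume(arr, spacing = abs(sp), origin = c(0, 0, 0))
}

#' @rdname read_volume
#' @param x an `image_volume` (masks may be logical; they are written as uint8).
#' @param mask logical; write as an unsigned 8-bit label map.
#' @export
write_volume <- function(x, path, mask = FALSE) {
  dat <- x$data
  ref <- list(pixdim = c(-1, x$spacing, 0, 0, 0, 0))
  if (mask) {
    storage.mode(dat) <- "integer"
    img <- RNifti::asNifti(dat, reference = ref, datatype = "uint8")
  } else {
    img <- RNifti::asNifti(dat, reference = ref)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
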