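#' Rigid (6-DOF) spatial transforms
#'
#' A `rigid_transform` acts on world coordinates (mm) as
#' `p -> R (p - center) + center + translation`, where `R` is a 3x3 rotation
#' matrix. Rotations may be given either as a matrix or as three Euler angles
#' (radians) applied in x-y-z order, `R = Rz(c) %*% Ry(b) %*% Rx(a)`.
#'
#' Used to express the inter-visit misalignment of follow-up scans and its
#' correction: [estimate_rigid()] returns the transform that maps the moving
#' volume into the fixed frame, i.e. `resample_volume(moving, t)` is aligned
#' with `fixed`.
#'
#' @param angles rotation angles (radians) about x, y, z; ignored when
#'   `rotation` is supplied.
#' @param translation translation in mm (length 3).
#' @param center rotation centre in mm (length 3).
#' @param rotation optional 3x3 orthonormal rotation matrix.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   (matrix), `angles`, `translation` and `center`.
#' @examples
#' t1 <- rigid_transform(angles = c(0, 0, pi / 36), translation = c(2, -1, 1.5))
#' p <- matrix(c(10, 10, 10), ncol = 3)
#' transform_points(compose_transforms(invert_transform(t1), t1), p) # == p
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0), rotation = NULL) {
  if (is.null(rotation)) {
    stopifnot(length(angles) == 3L)
    rotation <- euler_to_matrix(angles)
  } else {
    rotation <- as.matrix(rotation)
    if (!all(dim(rotation) == c(3L, 3L)) ||
        max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
        abs(det(rotation) - 1) > 1e-9) {
      abort("`rotation` must be a proper orthonormal 3x3 matrix (tolerance 1e-9).")
    }
    angles <- matrix_to_euler(rotation)
  }
  stopifnot(length(translation) == 3L, length(center) == 3L)
  structure(
    list(rotation = rotation, angles = as.numeric(angles),
         translation = as.numeric(translation), center = as.numeric(center)),
    class = "rigid_transform"
  )
}

euler_to_matrix <- function(angles) {
  ca <- cos(angles[1]); sa <- sin(angles[1])
  cb <- cos(angles[2]); sb <- sin(angles[2])
  cc <- cos(angles[3]); sc <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  rz <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

matrix_to_euler <- function(r) {
  # inverse of euler_to_matrix for |beta| < pi/2 (ample for small misalignments)
  beta <- asin(-r[3, 1])
  alpha <- atan2(r[3, 2], r[3, 3])
  gamma <- atan2(r[2, 1], r[1, 1])
  c(alpha, beta, gamma)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> angles (deg): %s | translation (mm): %s | center (mm): %s\n",
    paste(signif(x$angles * 180 / pi, 4), collapse = ", "),
    paste(signif(x$translation, 4), collapse = ", "),
    paste(signif(x$center, 4), collapse = ", ")
  ))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points an n-by-3 matrix (or length-3 vector) of mm coordinates.
#' @return An n-by-3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, points) {
  p <- matrix(points, ncol = 3)
  centred <- sweep(p, 2, transform$center, "-")
  out <- centred %*% t(transform$rotation)
  sweep(out, 2, transform$center + transform$translation, "+")
}

#' @rdname transform_points
#' @export
invert_transform <- function(transform) {
  r <- t(transform$rotation)
  rigid_transform(
    rotation = r,
    translation = as.numeric(-r %*% transform$translation),
    center = transform$center
  )
}

#' @rdname transform_points
#' @param a,b transforms; the composite applies `b` first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  # q = Ra (Rb (p - cb) + cb + tb - ca) + ca + ta, expressed about centre cb
  r <- a$rotation %*% b$rotation
  t_new <- as.numeric(
    a$rotation %*% (b$center + b$translation - a$center) +
      a$center + a$translation - b$center
  )
  rigid_transform(rotation = r, translation = t_new, center = b$center)
}

is_identity_transform <- function(transform, tol = 1e-12) {
  max(abs(transform$rotation - diag(3))) < tol &&
    max(abs(transform$translation)) < tol
}

#' Target registration error
#'
#' Mean Euclidean distance (mm) between corresponding points mapped by the
#' true and the estimated transform: the standard summary of how far a
#' registration is from ground truth at the locations that matter (e.g. ROI
#' corners or tooth sites).
#'
#' @param t_true,t_est [rigid_transform()] objects.
#' @param points an n-by-3 matrix of evaluation points in mm (at least one).
#' @return Mean distance in mm (single number).
#' @export
target_registration_error <- function(t_true, t_est, points) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 1L) abort("`points` must contain at least one point.")
  d <- transform_points(t_true, points) - transform_points(t_est, points)
  mean(sqrt(rowSums(d^2)))
}

#' Serialize rigid transforms as JSON
#'
#' The JSON records the Euler angles (radians), translation, centre and the
#' convention string, so files are self-describing.
#'
#' @param transform a [rigid_transform()].
#' @param path output (input) file path.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(
      convention = "point -> Rz*Ry*Rx (p - center) + center + translation; mm; radians",
      angles = transform$angles,
      translation = transform$translation,
      center = transform$center
    ),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(angles = x$angles, translation = x$translation, center = x$center)
}
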