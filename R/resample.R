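#' Sample a volume at arbitrary world coordinates
#'
#' @param volume an [image_volume()].
#' @param points n-by-3 matrix of mm coordinates.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill value returned for points outside the volume.
#' @return Numeric vector of sampled values.
#' @export
sample_volume <- function(volume, points,
                          interpolation = c("trilinear", "nearest"),
                          fill = 0) {
  interpolation <- match.arg(interpolation)
  d <- dim(volume$data)
  ci <- world_to_index(volume, points)
  out <- rep(as.numeric(fill), nrow(ci))

  if (interpolation == "nearest") {
    ri <- round(ci)
    ok <- index_in_grid(ri, d)
    if (any(ok)) {
      lin <- (ri[ok, 3] - 1) * d[1] * d[2] + (ri[ok, 2] - 1) * d[1] + ri[ok, 1]
      out[ok] <- volume$data[lin]
    }
    return(out)
  }

  # trilinear: clamp the 1/2-voxel border so samples exactly on the boundary
  # voxel centres interpolate rather than fall outside
  ok <- index_in_grid(ci, d, tol = 1e-9)
  if (!any(ok)) return(out)
  p <- ci[ok, , drop = FALSE]
  p[, 1] <- pmin(pmax(p[, 1], 1), d[1])
  p[, 2] <- pmin(pmax(p[, 2], 1), d[2])
  p[, 3] <- pmin(pmax(p[, 3], 1), d[3])
  f <- floor(p)
  f[, 1] <- pmin(f[, 1], d[1] - 1L); f[, 2] <- pmin(f[, 2], d[2] - 1L)
  f[, 3] <- pmin(f[, 3], d[3] - 1L)
  w <- p - f
  arr <- volume$data
  n12 <- d[1] * d[2]
  base <- (f[, 3] - 1) * n12 + (f[, 2] - 1) * d[1] + f[, 1]
  v000 <- arr[base]
  v100 <- arr[base + 1]
  v010 <- arr[base + d[1]]
  v110 <- arr[base + d[1] + 1]
  v001 <- arr[base + n12]
  v101 <- arr[base + n12 + 1]
  v011 <- arr[base + n12 + d[1]]
  v111 <- arr[base + n12 + d[1] + 1]
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  c00 <- v000 * (1 - wx) + v100 * wx
  c10 <- v010 * (1 - wx) + v110 * wx
  c01 <- v001 * (1 - wx) + v101 * wx
  c11 <- v011 * (1 - wx) + v111 * wx
  c0 <- c00 * (1 - wy) + c10 * wy
  c1 <- c01 * (1 - wy) + c11 * wy
  out[ok] <- c0 * (1 - wz) + c1 * wz
  out
}

#' Resample a volume through a rigid transform
#'
#' Pushes the image forward through `transform`: the output voxel at world
#' position `x` takes the source value at `transform^{-1}(x)`, so the image
#' content moves with the transform. Resampling the moving scan with the
#' transform returned by [estimate_rigid()] therefore aligns it onto the
#' fixed scan. Output is on `grid` (the input grid by default); points that
#' map outside the source domain receive `fill`. Use `"nearest"` for label
#' masks and `"trilinear"` for intensity volumes.
#'
#' @param volume an [image_volume()] to resample.
#' @param transform a [rigid_transform()].
#' @param interpolation `"trilinear"` (intensities) or `"nearest"` (masks).
#' @param fill value assigned outside the source domain.
#' @param grid optional `image_volume` whose grid defines the output lattice.
#' @return An `image_volume` on the target grid.
#' @export
resample_volume <- function(volume, transform,
                            interpolation = c("trilinear", "nearest"),
                            fill = 0, grid = volume) {
  interpolation <- match.arg(interpolation)
  inv <- invert_transform(transform)
  pts <- transform_points(inv, voxel_centers(grid))
  vals <- sample_volume(volume, pts, interpolation = interpolation, fill = fill)
  image_volume(array(vals, dim(grid$data)), spacing = grid$spacing,
               origin = grid$origin)
}
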