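#' Options for rigid registration
#'
#' @param levels integer shrink factors of the multi-resolution pyramid,
#'   coarse to fine; levels whose downsampled grid would fall below 8 voxels
#'   on any axis are skipped automatically.
#' @param metric `"msd"` (mean squared intensity difference; default, for
#'   same-contrast pairs) or `"ncc"` (one minus Pearson correlation, for
#'   cross-contrast pairs).
#' @param maxit iteration cap per level (recycled across levels).
#' @param reltol relative convergence tolerance of the optimizer.
#' @param init optional initial [rigid_transform()].
#' @return A `register_options` list.
#' @export
register_options <- function(levels = c(4, 2, 1), metric = c("msd", "ncc"),
                             maxit = c(600, 500, 800), reltol = 1e-7,
                             smooth_sigma_vox = 0.8,
                             init_search_mm = 6, init_search_step_mm = 1.5,
                             init = NULL) {
  metric <- match.arg(metric)
  structure(list(levels = as.integer(levels), metric = metric,
                 maxit = rep_len(as.integer(maxit), length(levels)),
                 reltol = reltol, smooth_sigma_vox = smooth_sigma_vox,
                 init_search_mm = init_search_mm,
                 init_search_step_mm = init_search_step_mm,
                 init = init),
            class = "register_options")
}

# separable Gaussian smoothing (replicate-padded), sigma in voxels
gaussian_smooth_volume <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  half <- max(1L, ceiling(2.5 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  smooth_axis <- function(arr, axis) {
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = d[axis])
    padded <- rbind(m[rep(1L, half), , drop = FALSE], m,
                    m[rep(nrow(m), half), , drop = FALSE])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(k)) {
      out <- out + k[o] * padded[(o - 1) + seq_len(n), , drop = FALSE]
    }
    aperm(array(out, d[perm]), order(perm))
  }
  arr <- smooth_axis(smooth_axis(smooth_axis(vol$data, 1), 2), 3)
  image_volume(arr, spacing = vol$spacing, origin = vol$origin)
}

# block-mean downsampling by an integer factor (crops trailing voxels)
downsample_volume <- function(vol, f) {
  if (f <= 1L) return(vol)
  d <- dim(vol$data)
  dn <- d %/% f
  arr <- vol$data[seq_len(dn[1] * f), seq_len(dn[2] * f), seq_len(dn[3] * f)]
  dim(arr) <- c(f, dn[1], f, dn[2], f, dn[3])
  out <- apply(arr, c(2, 4, 6), mean)
  # voxel centres of each block sit at the mean of the constituent centres
  image_volume(out, spacing = vol$spacing * f,
               origin = vol$origin + (f - 1) / 2 * vol$spacing)
}

registration_metric <- function(par, fixed_vals, moving, pts, center, metric) {
  tr <- rigid_transform(angles = par[1:3], translation = par[4:6], center = center)
  mv <- sample_volume(moving, transform_points(invert_transform(tr), pts),
                      interpolation = "trilinear", fill = NA)
  ok <- !is.na(mv)
  if (mean(ok) < 0.25) return(.Machine$double.xmax / 1e6)
  if (metric == "msd") {
    mean((fixed_vals[ok] - mv[ok])^2)
  } else {
    1 - suppressWarnings(stats::cor(fixed_vals[ok], mv[ok]))
  }
}

#' Estimate a rigid transform between two volumes
#'
#' Deterministic multi-resolution intensity-based rigid registration: at
#' each pyramid level (block-mean downsampling), the six transform
#' parameters (three Euler angles about the fixed-volume centre, three
#' translations) are refined by Nelder-Mead descent on the similarity
#' metric, evaluated by trilinear resampling of the moving volume over the
#' fixed grid. There is no stochastic sampling, so results are reproducible
#' bit-for-bit for fixed inputs and options.
#'
#' @param fixed,moving [image_volume()]s with overlapping content.
#' @param options a [register_options()].
#' @return A `rigid_registration` object: `transform` (the
#'   [rigid_transform()] mapping `moving` into the fixed frame, i.e.
#'   `resample_volume(moving, transform)` aligns with `fixed`), `converged`,
#'   `metric_value`, `metric`, `levels_used` and `iterations`. Errors if the
#'   volumes do not overlap at initialization; carries `converged = FALSE`
#'   (with a warning) when the iteration cap is hit at the finest level.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_config(
#'   grid_shape = c(32, 32, 28), noise_sd = 0,
#'   lesions_t0 = list(lesion(c(10, 10, 9), 3, 6)),
#'   lesions_t1 = list(lesion(c(10, 10, 9), 3, 6)),
#'   true_transform = rigid_transform(angles = c(0, 0, 0.03),
#'                                    translation = c(1, -0.5, 0.7),
#'                                    center = c(10, 10, 9))
#' ))
#' reg <- estimate_rigid(ph$stir_t0, ph$stir_t1)
#' }
#' @export
estimate_rigid <- function(fixed, moving, options = register_options()) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  center <- fixed$origin + (dim(fixed$data) - 1) / 2 * fixed$spacing
  init <- options$init
  par <- if (is.null(init)) rep(0, 6) else c(init$angles, init$translation)

  # overlap sanity check at initialization
  pts0 <- voxel_centers(fixed)
  tr0 <- rigid_transform(angles = par[1:3], translation = par[4:6], center = center)
  v0 <- sample_volume(moving, transform_points(invert_transform(tr0), pts0),
                      interpolation = "nearest", fill = NA)
  if (mean(!is.na(v0)) < 0.05) {
    abort("fixed and moving volumes do not overlap at initialization.")
  }

  levels_used <- integer(0)
  iterations <- integer(0)
  converged <- TRUE
  value <- NA_real_
  first_level <- TRUE
  for (li in seq_along(options$levels)) {
    f <- options$levels[li]
    if (any(dim(fixed$data) %/% f < 8)) next
    fx <- gaussian_smooth_volume(downsample_volume(fixed, f),
                                 options$smooth_sigma_vox)
    mv <- gaussian_smooth_volume(downsample_volume(moving, f),
                                 options$smooth_sigma_vox)
    pts <- voxel_centers(fx)
    fvals <- as.numeric(fx$data)
    if (first_level && options$init_search_mm > 0) {
      # deterministic translation grid search to seed the coarsest level,
      # immune to the flat/locally rough metric around the start
      steps <- seq(-options$init_search_mm, options$init_search_mm,
                   by = options$init_search_step_mm)
      grid <- as.matrix(expand.grid(tx = steps, ty = steps, tz = steps))
      vals <- apply(grid, 1, function(tt) {
        registration_metric(c(par[1:3], par[4:6] + tt), fvals, mv, pts,
                            center, options$metric)
      })
      par[4:6] <- par[4:6] + grid[which.min(vals), ]
      first_level <- FALSE
    }
    opt <- optim(
      par, registration_metric,
      fixed_vals = fvals, moving = mv, pts = pts, center = center,
      metric = options$metric,
      method = "Nelder-Mead",
      control = list(maxit = options$maxit[li], reltol = options$reltol,
                     parscale = c(rep(0.02, 3), rep(1, 3)))
    )
    par <- opt$par
    value <- opt$value
    levels_used <- c(levels_used, f)
    iterations <- c(iterations, opt$counts[1])
    if (li == length(options$levels) && opt$convergence != 0) {
      converged <- FALSE
      warn("registration hit the iteration cap at the finest level; result may be unconverged.")
    }
  }
  structure(
    list(
      transform = rigid_transform(angles = par[1:3], translation = par[4:6],
                                  center = center),
      converged = converged, metric_value = value, metric = options$metric,
      levels_used = levels_used, iterations = iterations
    ),
    class = "rigid_registration"
  )
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat(sprintf("<rigid_registration> metric %s = %.6g, %s\n", x$metric,
              x$metric_value,
              if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  invisible(x)
}

#' @export
glance.rigid_registration <- function(x, ...) {
  tibble(
    metric = x$metric, metric_value = x$metric_value,
    converged = x$converged,
    levels = paste(x$levels_used, collapse = "/"),
    iterations = sum(x$iterations),
    rot_deg = sqrt(sum(x$transform$angles^2)) * 180 / pi,
    trans_mm = sqrt(sum(x$transform$translation^2))
  )
}
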