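#' Configure a synthetic jaw phantom
#'
#' The phantom emulates the imaging substrate of the study: a fat-suppressed
#' (STIR-like) volume in which marrow edema is hyperintense, and a
#' black-bone (T1-like) companion in which cortical bone is hypointense,
#' both on an isotropic 0.65 mm grid, at two visits separated by a known
#' rigid misalignment. Geometry is deliberately schematic (a cortical box
#' shell around a marrow slab split into four quadrants, with molar probing
#' sites on the alveolar crest); it is a test substrate, not an anatomical
#' model.
#'
#' Intensity units are arbitrary: `marrow_sd` defines the unit in which
#' lesion contrast and the classification threshold are expressed, while
#' `noise_sd` (defaulting to `marrow_sd`) sets the amplitude of the noise
#' actually added, so noiseless phantoms with well-defined lesion contrast
#' are possible. The default `marrow_mean`/`marrow_sd` of 100/10 gives
#' SNR 10.
#'
#' @param grid_shape voxels per axis (3 integers).
#' @param voxel_size_mm isotropic voxel spacing in mm (default 0.65).
#' @param marrow_mean reference marrow signal level (arbitrary units).
#' @param marrow_sd reference marrow SD: the unit of lesion contrast and of
#'   the `> k` SD classification rule.
#' @param noise_sd SD of the added scanner noise; defaults to `marrow_sd`,
#'   set to 0 for noiseless phantoms.
#' @param lesions_t0,lesions_t1 lists of [lesion()] specs per timepoint.
#' @param true_transform the rigid misalignment applied to the follow-up
#'   volumes (a [rigid_transform()]); registration should recover its
#'   inverse.
#' @param noise_model `"gaussian"` (default; makes the analytic normal-tail
#'   false-positive rate of the SD rule exact) or `"rician"` (magnitude-MRI
#'   noise, approximately Gaussian at high SNR).
#' @param n_teeth number of molar teeth carrying probing sites (placed along
#'   the ridge midline).
#' @param seed integer seed; identical configs and seeds give bit-identical
#'   bundles.
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 48),
                           voxel_size_mm = 0.65,
                           marrow_mean = 100,
                           marrow_sd = 10,
                           noise_sd = marrow_sd,
                           lesions_t0 = list(),
                           lesions_t1 = list(),
                           true_transform = rigid_transform(),
                           noise_model = c("gaussian", "rician"),
                           n_teeth = 4,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L)) {
    abort("`grid_shape` must be 3 integers, each at least 16.")
  }
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0) {
    abort("`voxel_size_mm` must be positive.")
  }
  if (marrow_sd < 0 || noise_sd < 0) abort("SD parameters must be non-negative.")
  cfg <- structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         marrow_mean = marrow_mean, marrow_sd = marrow_sd, noise_sd = noise_sd,
         lesions_t0 = lesions_t0, lesions_t1 = lesions_t1,
         true_transform = true_transform, noise_model = noise_model,
         n_teeth = as.integer(n_teeth), seed = as.integer(seed)),
    class = "phantom_config"
  )
  geom <- phantom_geometry(cfg)
  for (tp in c("t0", "t1")) {
    les <- cfg[[paste0("lesions_", tp)]]
    for (i in seq_along(les)) {
      l <- les[[i]]
      stopifnot(inherits(l, "phantom_lesion"))
      lo <- l$center - l$semi_axes - voxel_size_mm
      hi <- l$center + l$semi_axes + voxel_size_mm
      if (any(lo < geom$marrow_lo_mm) || any(hi > geom$marrow_hi_mm)) {
        abort(sprintf(
          "lesion %d at %s does not fit inside the marrow compartment (%s to %s mm).",
          i, tp, paste(signif(geom$marrow_lo_mm, 4), collapse = ","),
          paste(signif(geom$marrow_hi_mm, 4), collapse = ",")
        ))
      }
    }
  }
  cfg
}

#' @rdname phantom_config
#' @param center,semi_axes ellipsoid centre and semi-axes in mm (world
#'   coordinates).
#' @param contrast_sd lesion contrast in units of `marrow_sd`; lesions meant
#'   to be detected by the `> 2` SD rule need `contrast_sd > 2`.
#' @export
lesion <- function(center, semi_axes, contrast_sd) {
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3L)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L)
  if (any(semi_axes <= 0)) abort("`semi_axes` must be positive.")
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 contrast_sd = as.numeric(contrast_sd)),
            class = "phantom_lesion")
}

# Schematic jaw geometry shared by generation and validation: a cortical box
# shell (2 voxels thick) enclosing a marrow slab, 3 voxels of air margin.
phantom_geometry <- function(cfg) {
  d <- cfg$grid_shape
  sp <- cfg$voxel_size_mm
  margin <- 3L; shell <- 2L
  bone_lo <- c(margin, margin, margin) + 1L              # 1-based index bounds
  bone_hi <- c(d[1] - margin, d[2] - margin, round(0.72 * d[3]))
  marrow_lo <- bone_lo + shell
  marrow_hi <- bone_hi - shell
  list(
    margin = margin, shell = shell,
    bone_lo = bone_lo, bone_hi = bone_hi,
    marrow_lo = marrow_lo, marrow_hi = marrow_hi,
    marrow_lo_mm = (marrow_lo - 1) * sp,
    marrow_hi_mm = (marrow_hi - 1) * sp,
    crest_z_mm = (marrow_hi[3] - 1) * sp
  )
}

box_mask <- function(d, lo, hi) {
  m <- array(FALSE, d)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

# normalized ellipsoid radius field over the voxel-centre lattice
lesion_radius_field <- function(cfg, l) {
  d <- cfg$grid_shape; sp <- cfg$voxel_size_mm
  x <- ((seq_len(d[1]) - 1) * sp - l$center[1]) / l$semi_axes[1]
  y <- ((seq_len(d[2]) - 1) * sp - l$center[2]) / l$semi_axes[2]
  z <- ((seq_len(d[3]) - 1) * sp - l$center[3]) / l$semi_axes[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  sqrt(r2)
}

# raised-cosine blend weight: 1 inside, 0 outside, smooth over ~1 voxel
lesion_weight <- function(cfg, l) {
  m <- lesion_radius_field(cfg, l)
  r_eff <- exp(mean(log(l$semi_axes)))
  dmm <- (m - 1) * r_eff
  w <- cfg$voxel_size_mm
  out <- array(0, dim(m))
  out[dmm <= -w / 2] <- 1
  band <- dmm > -w / 2 & dmm < w / 2
  out[band] <- 0.5 * (1 + cos(pi * (dmm[band] + w / 2) / w))
  out
}

lesion_truth_mask <- function(cfg, lesions) {
  m <- array(FALSE, cfg$grid_shape)
  for (l in lesions) m <- m | (lesion_radius_field(cfg, l) <= 1)
  m
}

lesion_contrast_field <- function(cfg, lesions) {
  f <- array(0, cfg$grid_shape)
  for (l in lesions) f <- pmax(f, l$contrast_sd * lesion_weight(cfg, l))
  f
}

# Longest contiguous intersection (mm) of the ray p(t) = crest + t*dir, t>=0,
# with a union of ellipsoids: the analytic ground truth for edema depth.
ray_lesion_run <- function(crest, dir, lesions) {
  iv <- list()
  for (l in lesions) {
    u <- (crest - l$center) / l$semi_axes
    v <- dir / l$semi_axes
    a <- sum(v^2); b <- 2 * sum(u * v); cc <- sum(u^2) - 1
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) next
    t1 <- (-b - sqrt(disc)) / (2 * a); t2 <- (-b + sqrt(disc)) / (2 * a)
    t1 <- max(t1, 0)
    if (t2 > t1) iv[[length(iv) + 1]] <- c(t1, t2)
  }
  if (!length(iv)) return(0)
  iv <- iv[order(vapply(iv, `[`, 0, 1))]
  merged <- list(iv[[1]])
  for (k in seq_along(iv)[-1]) {
    last <- merged[[length(merged)]]
    if (iv[[k]][1] <= last[2]) {
      merged[[length(merged)]][2] <- max(last[2], iv[[k]][2])
    } else merged[[length(merged) + 1]] <- iv[[k]]
  }
  max(vapply(merged, function(z) z[2] - z[1], 0))
}

phantom_sites <- function(cfg, geom) {
  sp <- cfg$voxel_size_mm
  n <- cfg$n_teeth
  x_lo <- geom$marrow_lo_mm[1]; x_hi <- geom$marrow_hi_mm[1]
  xc <- x_lo + (seq_len(n) - 0.5) * (x_hi - x_lo) / n
  y_mid <- mean(c(geom$marrow_lo_mm[2], geom$marrow_hi_mm[2]))
  y_off <- 0.22 * (geom$marrow_hi_mm[2] - geom$marrow_lo_mm[2])
  dx <- min(1.3, 0.3 * (x_hi - x_lo) / n)
  fdi <- c("36", "37", "38", "46", "47", "48", "26", "27")[seq_len(n)]
  rows <- list()
  for (i in seq_len(n)) {
    for (side in c("buccal", "lingual")) {
      yy <- y_mid + if (side == "buccal") y_off else -y_off
      for (pos in c("anterior", "mid", "posterior")) {
        xx <- xc[i] + switch(pos, anterior = -dx, mid = 0, posterior = dx)
        rows[[length(rows) + 1]] <- tibble(
          tooth_id = fdi[i],
          position = paste(side, pos, sep = "_"),
          crest_x = xx, crest_y = yy, crest_z = geom$crest_z_mm,
          apical_x = 0, apical_y = 0, apical_z = -1
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

add_noise <- function(arr, cfg) {
  if (cfg$noise_sd == 0) return(arr)
  if (cfg$noise_model == "gaussian") {
    arr + array(rnorm(length(arr), 0, cfg$noise_sd), dim(arr))
  } else {
    e1 <- array(rnorm(length(arr), 0, cfg$noise_sd), dim(arr))
    e2 <- array(rnorm(length(arr), 0, cfg$noise_sd), dim(arr))
    sqrt((arr + e1)^2 + e2^2)
  }
}

#' Generate a ground-truthed phantom bundle
#'
#' Builds the paired STIR-like and black-bone-like volumes at both
#' timepoints, the quadrant ROI masks, an edema-free reference-marrow mask,
#' the bone mask, the tooth probing sites, and the full ground truth (lesion
#' masks, volumes in mm^3, analytic per-site depths, and the true
#' misalignment). Follow-up volumes are resampled through
#' `config$true_transform` before noise is added, so the two visits carry
#' independent noise realizations, as in repeated scanning.
#'
#' @param config a [phantom_config()].
#' @return A `phantom_bundle`: volumes, masks (`image_volume`s with logical
#'   data), a `sites` tibble, and a `truth` list with `lesion_mask_t0`,
#'   `lesion_mask_t1`, `volumes` (tibble of mm^3 per timepoint),
#'   `site_depths` (tibble of analytic depths per site and timepoint) and
#'   `true_transform`.
#' @examples
#' cfg <- phantom_config(
#'   grid_shape = c(32, 32, 28), noise_sd = 0,
#'   lesions_t0 = list(lesion(c(10, 10, 9), 3, contrast_sd = 6)), seed = 7
#' )
#' ph <- generate_phantom(cfg)
#' ph$truth$volumes
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  d <- cfg$grid_shape; sp <- cfg$voxel_size_mm
  geom <- phantom_geometry(cfg)
  vol <- function(arr) image_volume(arr, spacing = sp)

  bone <- box_mask(d, geom$bone_lo, geom$bone_hi)
  marrow <- box_mask(d, geom$marrow_lo, geom$marrow_hi)
  shell <- bone & !marrow

  # quadrant ROIs: marrow split at the x/y midlines
  xm <- floor(mean(c(geom$marrow_lo[1], geom$marrow_hi[1])))
  ym <- floor(mean(c(geom$marrow_lo[2], geom$marrow_hi[2])))
  ix <- slice.index(marrow, 1); iy <- slice.index(marrow, 2)
  roi_masks <- list(
    Q1 = vol(marrow & ix <= xm & iy <= ym),
    Q2 = vol(marrow & ix > xm & iy <= ym),
    Q3 = vol(marrow & ix <= xm & iy > ym),
    Q4 = vol(marrow & ix > xm & iy > ym)
  )

  scene_stir <- function(lesions) {
    arr <- array(0, d)
    arr[shell] <- 0.3 * cfg$marrow_mean
    arr[marrow] <- cfg$marrow_mean
    if (length(lesions)) {
      arr <- arr + cfg$marrow_sd * lesion_contrast_field(cfg, lesions)
    }
    arr
  }
  scene_t1bone <- function() {
    # soft tissue intermediate, cortical bone near-black, fatty marrow bright
    arr <- array(0.5 * cfg$marrow_mean, d)
    arr[shell] <- 0.05 * cfg$marrow_mean
    arr[marrow] <- 0.9 * cfg$marrow_mean
    arr
  }

  s0 <- scene_stir(cfg$lesions_t0)
  s1 <- scene_stir(cfg$lesions_t1)
  b0 <- scene_t1bone()

  mis <- cfg$true_transform
  if (is_identity_transform(mis)) {
    s1m <- s1; b1m <- b0
  } else {
    s1m <- resample_volume(vol(s1), mis, "trilinear", fill = 0)$data
    b1m <- resample_volume(vol(b0), mis, "trilinear", fill = 0)$data
  }

  stir_t0 <- vol(add_noise(s0, cfg))
  stir_t1 <- vol(add_noise(s1m, cfg))
  t1bone_t0 <- vol(add_noise(b0, cfg))
  t1bone_t1 <- vol(add_noise(b1m, cfg))

  # edema-free reference marrow: everything at least ~2 voxels + blend edge
  # away from any lesion of either visit
  ref <- marrow
  buffer_mm <- 2.5 * sp
  for (l in c(cfg$lesions_t0, cfg$lesions_t1)) {
    r_eff <- exp(mean(log(l$semi_axes)))
    ref <- ref & (lesion_radius_field(cfg, l) > 1 + buffer_mm / r_eff)
  }
  if (sum(ref) < 2) abort("reference marrow mask degenerate: lesions cover the marrow.")

  truth_m0 <- lesion_truth_mask(cfg, cfg$lesions_t0)
  truth_m1 <- lesion_truth_mask(cfg, cfg$lesions_t1)
  volumes <- tibble(
    timepoint = c("t0", "t1"),
    volume_mm3 = c(sum(truth_m0), sum(truth_m1)) * sp^3
  )

  sites <- phantom_sites(cfg, geom)
  depth_one <- function(row, lesions) {
    ray_lesion_run(c(row$crest_x, row$crest_y, row$crest_z),
                   c(row$apical_x, row$apical_y, row$apical_z), lesions)
  }
  site_depths <- dplyr::bind_rows(
    dplyr::mutate(sites, timepoint = "t0",
                  ed_mm = purrr::map_dbl(seq_len(nrow(sites)),
                                         ~ depth_one(sites[.x, ], cfg$lesions_t0))),
    dplyr::mutate(sites, timepoint = "t1",
                  ed_mm = purrr::map_dbl(seq_len(nrow(sites)),
                                         ~ depth_one(sites[.x, ], cfg$lesions_t1)))
  )
  site_depths <- dplyr::select(site_depths, "tooth_id", "position", "timepoint", "ed_mm")

  structure(
    list(
      stir_t0 = stir_t0, stir_t1 = stir_t1,
      t1bone_t0 = t1bone_t0, t1bone_t1 = t1bone_t1,
      roi_masks = roi_masks,
      marrow_ref_mask = vol(ref),
      bone_mask = vol(bone),
      marrow_mask = vol(marrow),
      sites = sites,
      truth = list(
        lesion_mask_t0 = vol(truth_m0), lesion_mask_t1 = vol(truth_m1),
        volumes = volumes, site_depths = site_depths,
        true_transform = cfg$true_transform
      ),
      config = cfg
    ),
    class = "phantom_bundle"
  )
}

#' @export
print.phantom_bundle <- function(x, ...) {
  d <- dim(x$stir_t0)
  cat(sprintf(
    "<phantom_bundle> %d x %d x %d voxels @ %.3g mm, %d + %d lesions, %d sites\n",
    d[1], d[2], d[3], x$config$voxel_size_mm,
    length(x$config$lesions_t0), length(x$config$lesions_t1), nrow(x$sites)
  ))
  print(x$truth$volumes)
  invisible(x)
}

#' Derive the osseous compartment from a black-bone volume
#'
#' Thresholds the hypointense cortical shell (below `cortical_frac` of the
#' volume's robust bright reference) and fills, per (x, y) column, everything
#' between the first and last cortical voxel. This column-fill closing is
#' adequate for the shell-like geometry the phantom produces; on real
#' anatomy the bone mask is a manual-segmentation input, not a derived one.
#'
#' @param t1bone an [image_volume()] with hypointense cortical bone.
#' @param cortical_frac intensity fraction below which a voxel is cortical.
#' @return An `image_volume` with a logical bone mask.
#' @export
derive_bone_mask <- function(t1bone, cortical_frac = 0.3) {
  # light smoothing so scanner noise cannot seed spurious cortical voxels
  arr <- gaussian_smooth_volume(t1bone, 0.5)$data
  bright <- quantile(arr, 0.9, names = FALSE)
  cort <- arr < cortical_frac * bright
  d <- dim(arr)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      w <- which(cort[i, j, ])
      if (length(w) >= 2L) out[i, j, min(w):max(w)] <- TRUE
    }
  }
  image_volume(out, spacing = t1bone$spacing, origin = t1bone$origin)
}
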