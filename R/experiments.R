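#' Parameter-recovery experiments on ground-truthed phantoms
#'
#' These functions bundle the package's standard validation studies:
#' each generates fully ground-truthed synthetic inputs, runs the actual
#' measurement pipeline on them, and reports estimate vs truth. They are the
#' package's evidence that the SD-threshold classifier, the volumetry, the
#' depth measurement and the registration behave as specified under
#' controlled conditions (see the methods vignette for what the phantoms do
#' and do not emulate).
#'
#' `experiment_null_fraction()` measures the false-positive floor of the
#' `> k` SD rule on a lesion-free Gaussian phantom, whose expected value is
#' the analytic normal tail `pnorm(k, lower.tail = FALSE)` (0.02275 at
#' `k = 2`).
#'
#' @param seed integer seed.
#' @param grid_shape phantom grid; the default gives an ROI of ~1.6e5
#'   marrow voxels.
#' @param k threshold multiplier.
#' @return A one-row tibble: `fraction` classified, `expected`, `n_roi`
#'   voxels and the binomial `se`.
#' @export
experiment_null_fraction <- function(seed = 1, grid_shape = c(80, 80, 56), k = 2) {
  ph <- generate_phantom(phantom_config(grid_shape = grid_shape, seed = seed))
  ref <- reference_stats(ph$stir_t0, ph$marrow_ref_mask)
  e <- classify_edema(ph$stir_t0, ph$marrow_mask, ph$bone_mask, ref, k = k)
  n_roi <- sum(ph$marrow_mask$data)
  p <- pnorm(k, lower.tail = FALSE)
  tibble(
    fraction = sum(e$mask$data) / n_roi,
    expected = p,
    n_roi = n_roi,
    se = sqrt(p * (1 - p) / n_roi)
  )
}

#' @rdname experiment_null_fraction
#' @details `experiment_volume_recovery()` plants single ellipsoidal lesions
#'   of 100-1000 mm^3 at +6 SD contrast in SNR-10 phantoms and compares the
#'   classified edema volume (with a 20 mm^3 minimum-cluster filter, which
#'   removes the salt-noise floor the null experiment quantifies) against
#'   the digitized ground-truth volume.
#' @param n_phantoms number of seeded phantoms.
#' @param contrast_sd lesion contrast in reference-SD units.
#' @param noise_sd scanner noise SD (reference SD is 10, so 10 means SNR 10).
#' @param min_cluster_mm3 minimum-cluster filter used by the recovery
#'   protocol.
#' @export
experiment_volume_recovery <- function(n_phantoms = 20, seed = 1,
                                       contrast_sd = 6, noise_sd = 10,
                                       min_cluster_mm3 = 20) {
  targets <- seq(100, 1000, length.out = n_phantoms)
  grid <- c(48, 48, 64)
  g <- phantom_geometry(phantom_config(grid_shape = grid, seed = 1))
  ctr <- (g$marrow_lo_mm + g$marrow_hi_mm) / 2
  purrr::map_dfr(seq_len(n_phantoms), function(i) {
    r <- (3 * targets[i] / (4 * pi))^(1 / 3)
    cfg <- phantom_config(
      grid_shape = grid, noise_sd = noise_sd,
      lesions_t0 = list(lesion(ctr, r, contrast_sd)),
      seed = seed * 1000L + i
    )
    ph <- generate_phantom(cfg)
    ref <- reference_stats(ph$stir_t0, ph$marrow_ref_mask)
    e <- classify_edema(ph$stir_t0, ph$marrow_mask, ph$bone_mask, ref,
                        min_cluster_mm3 = min_cluster_mm3)
    truth <- ph$truth$volumes$volume_mm3[1]
    est <- edema_volume_mm3(e)
    tibble(target_mm3 = targets[i], truth_mm3 = truth, estimated_mm3 = est,
           rel_error = (est - truth) / truth)
  })
}

#' @rdname experiment_null_fraction
#' @details `experiment_change_recovery()` shrinks a lesion between visits
#'   (radius `r0` to `r1`, same centre) and checks the subtraction logic:
#'   the reported reduction volume should match the analytic shell
#'   `4/3 pi (r0^3 - r1^3)` and essentially no "new" edema should appear.
#' @param r0,r1 baseline and follow-up lesion radii (mm).
#' @export
experiment_change_recovery <- function(seed = 1, r0 = 6, r1 = 4.5,
                                       contrast_sd = 6, noise_sd = 10,
                                       min_cluster_mm3 = 20) {
  grid <- c(48, 48, 64)
  g <- phantom_geometry(phantom_config(grid_shape = grid, seed = 1))
  ctr <- (g$marrow_lo_mm + g$marrow_hi_mm) / 2
  cfg <- phantom_config(
    grid_shape = grid, noise_sd = noise_sd,
    lesions_t0 = list(lesion(ctr, r0, contrast_sd)),
    lesions_t1 = list(lesion(ctr, r1, contrast_sd)),
    seed = seed
  )
  ph <- generate_phantom(cfg)
  ref0 <- reference_stats(ph$stir_t0, ph$marrow_ref_mask)
  ref1 <- reference_stats(ph$stir_t1, ph$marrow_ref_mask)
  e0 <- classify_edema(ph$stir_t0, ph$marrow_mask, ph$bone_mask, ref0,
                       min_cluster_mm3 = min_cluster_mm3, roi_id = "all",
                       timepoint = "t0")
  e1 <- classify_edema(ph$stir_t1, ph$marrow_mask, ph$bone_mask, ref1,
                       min_cluster_mm3 = min_cluster_mm3, roi_id = "all",
                       timepoint = "t1")
  ch <- change_maps(e0, e1)$report
  shell <- 4 / 3 * pi * (r0^3 - r1^3)
  dplyr::mutate(ch, shell_mm3 = shell,
                reduction_rel_error = (.data$reduction_mm3 - shell) / shell,
                new_frac_of_shell = .data$new_mm3 / shell)
}

#' @rdname experiment_null_fraction
#' @details `experiment_depth_recovery()` plants lesions of known
#'   apical-coronal extent directly under a probing site and compares the
#'   measured edema depth with the planted extent. With `noise_sd = 0` the
#'   reference statistics are supplied analytically (nothing to estimate in
#'   a noiseless image) and recovery is limited only by digitization; at
#'   SNR 10 the full estimation path is used with a small (5 mm^3)
#'   minimum-cluster filter.
#' @param extents_mm true apical-coronal lesion extents (mm).
#' @export
experiment_depth_recovery <- function(seed = 1, extents_mm = 1:8,
                                      noise_sd = 10, contrast_sd = 6) {
  grid <- c(48, 48, 64)
  cfg0 <- phantom_config(grid_shape = grid, seed = 1)
  g <- phantom_geometry(cfg0)
  ph0 <- generate_phantom(cfg0)
  site <- ph0$sites[8, ]  # interior tooth, buccal_mid
  purrr::map_dfr(seq_along(extents_mm), function(i) {
    ext <- extents_mm[i]
    ctr <- c(site$crest_x, site$crest_y, g$crest_z_mm - ext / 2 - 2)
    cfg <- phantom_config(
      grid_shape = grid, noise_sd = noise_sd,
      lesions_t0 = list(lesion(ctr, c(2, 2, ext / 2), contrast_sd)),
      seed = seed * 500L + i
    )
    ph <- generate_phantom(cfg)
    ref <- if (noise_sd == 0) {
      manual_reference_stats(cfg$marrow_mean, cfg$marrow_sd)
    } else {
      reference_stats(ph$stir_t0, ph$marrow_ref_mask)
    }
    e <- classify_edema(ph$stir_t0, ph$marrow_mask, ph$bone_mask, ref,
                        min_cluster_mm3 = if (noise_sd == 0) 0 else 5)
    ed <- edema_depth(e, site)
    tibble(extent_mm = ext, measured_mm = ed, error_mm = ed - ext)
  })
}

#' @rdname experiment_null_fraction
#' @details `experiment_registration_recovery()` misaligns the follow-up
#'   scan of a noiseless lesioned phantom by known rigid transforms (up to
#'   5 degrees / 5 mm), re-estimates them, and reports the target
#'   registration error over the marrow-ROI corners.
#' @export
experiment_registration_recovery <- function(seed = 1) {
  deg <- pi / 180
  cases <- list(
    list(angles = c(0, 0, 5 * deg), translation = c(5, 0, 0)),
    list(angles = c(3 * deg, -2 * deg, 0), translation = c(2, -1, 1.5)),
    list(angles = c(0, 0, -2 * deg), translation = c(-3, 4, 2))
  )
  grid <- c(40, 40, 40)
  cfg0 <- phantom_config(grid_shape = grid, seed = 1)
  g <- phantom_geometry(cfg0)
  ctr <- (g$marrow_lo_mm + g$marrow_hi_mm) / 2
  corners <- as.matrix(expand.grid(c(g$marrow_lo_mm[1], g$marrow_hi_mm[1]),
                                   c(g$marrow_lo_mm[2], g$marrow_hi_mm[2]),
                                   c(g$marrow_lo_mm[3], g$marrow_hi_mm[3])))
  purrr::map_dfr(seq_along(cases), function(i) {
    mis <- rigid_transform(angles = cases[[i]]$angles,
                           translation = cases[[i]]$translation,
                           center = ctr)
    cfg <- phantom_config(
      grid_shape = grid, noise_sd = 0,
      lesions_t0 = list(lesion(ctr, 3, 6)),
      lesions_t1 = list(lesion(ctr, 3, 6)),
      true_transform = mis, seed = seed * 100L + i
    )
    ph <- generate_phantom(cfg)
    reg <- estimate_rigid(ph$stir_t0, ph$stir_t1)
    tre <- target_registration_error(invert_transform(mis), reg$transform, corners)
    tibble(case = i,
           rot_deg = sqrt(sum(cases[[i]]$angles^2)) / deg,
           trans_mm = sqrt(sum(cases[[i]]$translation^2)),
           tre_mm = tre, converged = reg$converged)
  })
}

#' @rdname experiment_null_fraction
#' @details `experiment_table_calibration()` simulates replicate cohorts of
#'   922 sites with the default clinical parameters, reads the PPD-band and
#'   edema-affected percentages back off the summary tables, and averages
#'   them over replicates (one cohort of 922 sites carries ~1.6 percentage
#'   points of binomial noise per band, so calibration is judged on the
#'   replicate mean at the cohort's own size, not on a single draw).
#' @param n_replicates number of simulated cohorts.
#' @export
experiment_table_calibration <- function(seed = 1, n_replicates = 30) {
  one <- function(s) {
    cfg <- clinical_sim_config(n_patients = 39, n_sites = 922, seed = s)
    rec <- generate_site_table(cfg)
    t2 <- as_tibble(build_table2(rec))
    t3 <- as_tibble(build_table3(rec))
    bands <- dplyr::filter(t2, .data$section == "category_counts")
    aff <- dplyr::filter(t3, .data$section == "affected_sites")
    cbind(c(bands$pct_t0, aff$pct_t0), c(bands$pct_t1, aff$pct_t1))
  }
  acc <- lapply(seq_len(n_replicates), function(r) one(seed * 11L + r))
  mean_pct <- Reduce(`+`, acc) / n_replicates
  tibble(
    stratum = c("PPD<=3", "PPD4-5", "PPD>=6", "edema affected"),
    pct_t0 = mean_pct[, 1],
    pct_t1 = mean_pct[, 2],
    # band targets are the configured category probabilities; the edema
    # targets are the analytic marginals of the presence/persistence model
    configured_t0 = c(52, 33, 15, 34.5),
    configured_t1 = c(57, 31, 12, 24.5),
    n_sites = 922,
    n_replicates = n_replicates
  )
}

#' @rdname experiment_null_fraction
#' @details `experiment_wilcoxon_power()` checks that, at the simulated
#'   cohort's size (~320 sites with baseline edema), the paired Wilcoxon
#'   detects the configured baseline-to-follow-up edema-depth shift; it
#'   returns the rejection rate at the 0.05 level over seeded replicates.
#' @param n_replicates number of simulated cohorts.
#' @export
experiment_wilcoxon_power <- function(n_replicates = 200, seed = 1) {
  hits <- vapply(seq_len(n_replicates), function(i) {
    rec <- generate_site_table(clinical_sim_config(n_patients = 39, n_sites = 922,
                                                   seed = seed * 7L + i))
    pr <- pair_records(rec)
    init <- which(pr$t0$edema_present == 1)
    p <- wilcoxon_paired(pr$t0$ed_mm[init], pr$t1$ed_mm[init])$p_value
    p < 0.05
  }, logical(1))
  tibble(n_replicates = n_replicates, power = mean(hits))
}
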