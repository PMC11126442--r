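#' Reference marrow signal statistics
#'
#' Estimates the mean and SD of healthy marrow signal inside an explicitly
#' edema-free reference mask. These statistics anchor the voxelwise
#' classification rule: a voxel is called edema when its signal exceeds
#' `mean + k * sd` (default `k = 2`). The `moment` estimator uses the sample
#' mean/SD; the `robust` estimator uses the median and 1.4826 x MAD, which
#' is SD-consistent under normality and tolerates residual bright voxels in
#' the reference region.
#'
#' @param stir an [image_volume()] (fat-suppressed, edema-hyperintense).
#' @param marrow_ref_mask mask (`image_volume` or logical array) of
#'   edema-free marrow; at least 2 voxels.
#' @param estimator `"moment"` or `"robust"`.
#' @return A `reference_stats` object: `mean`, `sd`, `n_voxels`, `estimator`,
#'   `degenerate` (TRUE when `sd` is 0, in which case classification refuses
#'   to run).
#' @export
reference_stats <- function(stir, marrow_ref_mask, estimator = c("moment", "robust")) {
  estimator <- match.arg(estimator)
  m <- mask_array(marrow_ref_mask)
  if (!identical(dim(m), dim(stir$data))) abort("mask is not on the image grid.")
  vals <- stir$data[m]
  if (length(vals) < 2L) abort("reference mask must contain at least 2 voxels.")
  if (estimator == "moment") {
    mu <- mean(vals); s <- sd(vals)
  } else {
    mu <- median(vals); s <- mad(vals, constant = 1.4826)
  }
  new_reference_stats(mu, s, length(vals), estimator)
}

#' @rdname reference_stats
#' @param mean,sd known reference statistics, e.g. the generating values of a
#'   noiseless phantom where estimation from the image is impossible.
#' @param n_voxels nominal support of the estimate.
#' @export
manual_reference_stats <- function(mean, sd, n_voxels = Inf) {
  new_reference_stats(mean, sd, n_voxels, "manual")
}

new_reference_stats <- function(mean, sd, n, estimator) {
  structure(
    list(mean = as.numeric(mean), sd = as.numeric(sd), n_voxels = n,
         estimator = estimator, degenerate = (sd <= 0)),
    class = "reference_stats"
  )
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> mean %.4g, sd %.4g (%s, n = %s)%s\n",
              x$mean, x$sd, x$estimator, format(x$n_voxels),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

mask_array <- function(x) {
  if (inherits(x, "image_volume")) x <- x$data
  if (!is.logical(x)) x <- x > 0.5
  x
}

#' Voxelwise edema classification by the SD rule
#'
#' Classifies a voxel as edema when its signal exceeds the reference marrow
#' mean by strictly more than `k` reference SDs (`k = 2` by default; ties at
#' exactly `k` SD are excluded). Classification is restricted to
#' `roi_mask & bone_mask`, so measurements stay within the osseous
#' compartment delineated on the black-bone sequence. Because the threshold
#' is expressed in each scan's own reference statistics, per-scan intensity
#' standardization (against scanner gain drift between visits) is built in.
#'
#' Under pure Gaussian noise the rule has an analytic false-positive rate of
#' `pnorm(k, lower.tail = FALSE)` (2.275% of the ROI at `k = 2`); the
#' optional `min_cluster_mm3` filter removes connected components
#' (6-connectivity) smaller than the given volume, which suppresses that
#' salt-noise floor. It defaults to 0 (off), matching a protocol that
#' applies no cluster filtering.
#'
#' @param stir an [image_volume()].
#' @param roi_mask quadrant ROI mask.
#' @param bone_mask osseous-compartment mask.
#' @param ref a [reference_stats()]; must not be degenerate.
#' @param k threshold multiplier in SD units (> 0).
#' @param min_cluster_mm3 minimum connected-component volume kept (0 = off).
#' @param roi_id,timepoint optional labels carried into the map.
#' @return An `edema_map`: logical `mask` (`image_volume`), `roi_id`,
#'   `timepoint`, `threshold_used` (signal units), `k`, `min_cluster_mm3`.
#' @export
classify_edema <- function(stir, roi_mask, bone_mask, ref, k = 2,
                           min_cluster_mm3 = 0,
                           roi_id = NA_character_, timepoint = NA_character_) {
  stopifnot(inherits(ref, "reference_stats"))
  if (ref$degenerate) abort("degenerate reference (sd = 0): cannot classify.")
  if (!is.numeric(k) || k <= 0) abort("`k` must be positive.")
  roi <- mask_array(roi_mask); bone <- mask_array(bone_mask)
  if (!identical(dim(roi), dim(stir$data)) || !identical(dim(bone), dim(stir$data))) {
    abort("masks are not on the image grid.")
  }
  thr <- ref$mean + k * ref$sd
  m <- roi & bone & (stir$data > thr)
  if (min_cluster_mm3 > 0 && any(m)) {
    min_vox <- ceiling(min_cluster_mm3 / prod(stir$spacing))
    m <- drop_small_components(m, min_vox)
  }
  structure(
    list(
      mask = image_volume(m, spacing = stir$spacing, origin = stir$origin),
      roi_id = roi_id, timepoint = timepoint,
      threshold_used = thr, k = k, min_cluster_mm3 = min_cluster_mm3
    ),
    class = "edema_map"
  )
}

#' @export
print.edema_map <- function(x, ...) {
  cat(sprintf(
    "<edema_map> %s voxels (%.4g mm^3), roi %s, timepoint %s, threshold %.4g (k = %g)\n",
    format(sum(x$mask$data)), sum(x$mask$data) * voxel_volume(x$mask),
    x$roi_id, x$timepoint, x$threshold_used, x$k
  ))
  invisible(x)
}

#' @rdname classify_edema
#' @param x an `edema_map`.
#' @export
edema_volume_mm3 <- function(x) {
  stopifnot(inherits(x, "edema_map"))
  sum(x$mask$data) * voxel_volume(x$mask)
}

# 6-connected component labelling by frontier BFS over the sparse foreground
label_components_3d <- function(mask) {
  d <- dim(mask)
  n12 <- d[1] * d[2]
  fg <- which(mask)
  labels <- integer(length(mask))
  if (!length(fg)) return(array(labels, d))
  current <- 0L
  seen <- logical(length(mask))
  idx <- arrayInd(fg, d)
  coord <- list(i = idx[, 1], j = idx[, 2], k = idx[, 3])
  names(coord) <- NULL
  in_fg <- logical(length(mask)); in_fg[fg] <- TRUE
  for (s in fg) {
    if (seen[s]) next
    current <- current + 1L
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      labels[frontier] <- current
      ii <- ((frontier - 1) %% d[1]) + 1
      jj <- (((frontier - 1) %/% d[1]) %% d[2]) + 1
      kk <- ((frontier - 1) %/% n12) + 1
      nb <- c(
        frontier[ii > 1] - 1L, frontier[ii < d[1]] + 1L,
        frontier[jj > 1] - d[1], frontier[jj < d[2]] + d[1],
        frontier[kk > 1] - n12, frontier[kk < d[3]] + n12
      )
      nb <- unique(nb[in_fg[nb] & !seen[nb]])
      seen[nb] <- TRUE
      frontier <- nb
    }
  }
  array(labels, d)
}

drop_small_components <- function(mask, min_vox) {
  lab <- label_components_3d(mask)
  if (!any(lab > 0)) return(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_vox)
  array(lab %in% keep, dim(mask))
}

#' Longitudinal change maps and per-quadrant volumetry
#'
#' Differences two co-registered edema maps of the same quadrant, mirroring
#' the two subtraction directions of a pre/post comparison: `reduction`
#' (edema at baseline no longer present at follow-up), `new` (edema present
#' only at follow-up) and `stable` (present at both). Volumes are voxel
#' counts times the voxel volume (0.65^3 mm^3 at default spacing), so
#' `reduction + stable` always equals the baseline edema volume and
#' `new + stable` the follow-up volume.
#'
#' @param e0 baseline `edema_map`.
#' @param e1_registered follow-up `edema_map`, computed after resampling the
#'   follow-up scan into the baseline frame.
#' @return An `edema_change` object: `report` (one-row tibble with
#'   `quadrant`, `reduction_mm3`, `new_mm3`, `stable_mm3`, `voxel_size_mm`)
#'   plus the `reduction_mask`, `new_mask` and `stable_mask` volumes.
#' @export
change_maps <- function(e0, e1_registered) {
  stopifnot(inherits(e0, "edema_map"), inherits(e1_registered, "edema_map"))
  if (!same_grid(e0$mask, e1_registered$mask)) {
    abort("edema maps are on different grids; register before differencing.")
  }
  m0 <- e0$mask$data; m1 <- e1_registered$mask$data
  vv <- voxel_volume(e0$mask)
  red <- m0 & !m1; new <- !m0 & m1; stab <- m0 & m1
  vol <- function(a) image_volume(a, spacing = e0$mask$spacing, origin = e0$mask$origin)
  structure(
    list(
      report = tibble(
        quadrant = e0$roi_id,
        reduction_mm3 = sum(red) * vv,
        new_mm3 = sum(new) * vv,
        stable_mm3 = sum(stab) * vv,
        voxel_size_mm = e0$mask$spacing[1]
      ),
      reduction_mask = vol(red), new_mask = vol(new), stable_mask = vol(stab)
    ),
    class = "edema_change"
  )
}

#' @export
print.edema_change <- function(x, ...) {
  cat("<edema_change>\n")
  print(x$report)
  invisible(x)
}

#' Subtraction-image change maps (alternative route)
#'
#' The alternative reading of a subtraction-based protocol: threshold the
#' voxelwise signal difference itself rather than differencing two
#' per-timepoint maps. The pre-minus-post subtraction highlights reduction,
#' post-minus-pre highlights new edema; each is thresholded at `k` SDs of
#' the difference noise (`sqrt(2)` times the single-scan reference SD).
#' Provided for comparison; the default pipeline differences per-timepoint
#' maps because the SD rule is defined against marrow signal, not signal
#' change.
#'
#' @inheritParams classify_edema
#' @param stir0,stir1_registered baseline scan and follow-up scan resampled
#'   into the baseline frame.
#' @param ref0,ref1 per-scan [reference_stats()]; signals are standardized by
#'   each scan's own reference before subtraction.
#' @return An `edema_change` object (see [change_maps()]); `stable_mm3` is 0
#'   by construction on this route.
#' @export
subtraction_change_maps <- function(stir0, stir1_registered, roi_mask, bone_mask,
                                    ref0, ref1, k = 2,
                                    roi_id = NA_character_) {
  if (ref0$degenerate || ref1$degenerate) abort("degenerate reference (sd = 0).")
  roi <- mask_array(roi_mask) & mask_array(bone_mask)
  z0 <- (stir0$data - ref0$mean) / ref0$sd
  z1 <- (stir1_registered$data - ref1$mean) / ref1$sd
  dz <- (z0 - z1) / sqrt(2)
  vv <- voxel_volume(stir0)
  red <- roi & (dz > k); new <- roi & (dz < -k)
  vol <- function(a) image_volume(a, spacing = stir0$spacing, origin = stir0$origin)
  structure(
    list(
      report = tibble(
        quadrant = roi_id,
        reduction_mm3 = sum(red) * vv,
        new_mm3 = sum(new) * vv,
        stable_mm3 = 0,
        voxel_size_mm = stir0$spacing[1]
      ),
      reduction_mask = vol(red), new_mask = vol(new),
      stable_mask = vol(array(FALSE, dim(stir0$data)))
    ),
    class = "edema_change"
  )
}

#' Edema depth along the apical-coronal site axis
#'
#' Measures the linear extent (mm) of classified edema along the probing
#' axis of a tooth site: the ray from the alveolar crest point in the apical
#' direction is sampled every `step_mm` (a quarter voxel by default, which
#' bounds digitization error well below one voxel), each sample looked up in
#' the edema map with nearest-voxel interpolation, and the depth is the
#' length of the longest contiguous run of edema-positive samples (0 when no
#' sample is positive). `rounding = "nearest_mm"` returns integer
#' millimetres for site records, matching probing-depth granularity.
#'
#' @param e an `edema_map`.
#' @param site a single site: a list or one-row data frame with `crest_x/y/z`
#'   and `apical_x/y/z` (mm; the apical vector is normalized internally).
#' @param step_mm ray sampling step; default `spacing / 4`.
#' @param rounding `"raw"` or `"nearest_mm"`.
#' @return Depth in mm (single number). If the ray never enters the grid, 0
#'   with a warning.
#' @export
edema_depth <- function(e, site, step_mm = NULL, rounding = c("raw", "nearest_mm")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(e, "edema_map"))
  crest <- as.numeric(c(site$crest_x, site$crest_y, site$crest_z))
  dirv <- as.numeric(c(site$apical_x, site$apical_y, site$apical_z))
  nrm <- sqrt(sum(dirv^2))
  if (nrm < 1e-9) abort("apical direction must be a non-zero vector.")
  dirv <- dirv / nrm
  if (is.null(step_mm)) step_mm <- e$mask$spacing[1] / 4
  d <- dim(e$mask$data)
  diag_mm <- sqrt(sum(((d - 1) * e$mask$spacing)^2))
  tt <- seq(0, diag_mm, by = step_mm)
  pts <- cbind(crest[1] + tt * dirv[1], crest[2] + tt * dirv[2],
               crest[3] + tt * dirv[3])
  inside <- index_in_grid(world_to_index(e$mask, pts), d, tol = 0.5)
  if (!any(inside)) {
    warn("site ray does not intersect the volume; depth set to 0.")
    return(0)
  }
  vals <- sample_volume(e$mask, pts, interpolation = "nearest", fill = 0)
  r <- rle(vals > 0.5)
  run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  ed <- run * step_mm
  if (rounding == "nearest_mm") ed <- round(ed)
  ed
}

#' Measure depths at many sites
#'
#' Vectorized wrapper around [edema_depth()] over a sites table.
#'
#' @param e an `edema_map`.
#' @param sites tibble with columns `tooth_id`, `position`, `crest_x/y/z`,
#'   `apical_x/y/z` (the layout produced by [generate_phantom()] and by
#'   [read_sites_csv()]).
#' @inheritParams edema_depth
#' @return The sites tibble with `ed_mm` (raw) and `ed_mm_rounded` columns.
#' @export
measure_site_depths <- function(e, sites, step_mm = NULL) {
  ed <- purrr::map_dbl(seq_len(nrow(sites)),
                       ~ edema_depth(e, sites[.x, ], step_mm = step_mm))
  dplyr::mutate(sites, ed_mm = ed, ed_mm_rounded = round(ed))
}

#' Per-tooth maximum edema depth
#'
#' The per-tooth summary used for comparison and testing: the maximum of the
#' (up to six) site depths of one tooth. Missing sites may be omitted or NA.
#'
#' @param site_depths numeric vector of 1 to 6 site depths (mm).
#' @return Maximum depth in mm.
#' @export
tooth_max_depth <- function(site_depths) {
  site_depths <- site_depths[!is.na(site_depths)]
  if (!length(site_depths)) abort("no site depths supplied.")
  if (length(site_depths) > 6L) abort("a tooth has at most 6 sites.")
  max(site_depths)
}

#' Read and write site definition tables
#'
#' Sites are stored as plain CSV with columns `tooth_id` (FDI notation),
#' `position` (buccal/lingual x anterior/mid/posterior), crest coordinates
#' and apical direction in mm.
#'
#' @param path CSV path.
#' @export
read_sites_csv <- function(path) {
  as_tibble(read.csv(path, colClasses = c(tooth_id = "character")))
}

#' @rdname read_sites_csv
#' @param sites a sites tibble.
#' @export
write_sites_csv <- function(sites, path) {
  write.csv(sites, path, row.names = FALSE)
  invisible(path)
}
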