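test_that("reference statistics estimate moments and flag degeneracy", {
  arr <- array(7, c(10, 10, 10))
  v <- image_volume(arr, spacing = 0.65)
  m <- array(TRUE, dim(arr))
  r <- reference_stats(v, m)
  expect_equal(r$mean, 7)
  expect_equal(r$sd, 0)
  expect_true(r$degenerate)
  expect_error(classify_edema(v, m, m, r), "degenerate")
  expect_error(reference_stats(v, array(FALSE, dim(arr))), "at least 2")

  set.seed(10)
  big <- image_volume(array(rnorm(1e5, 100, 10), c(50, 50, 40)), spacing = 0.65)
  mall <- array(TRUE, c(50, 50, 40))
  rs <- reference_stats(big, mall)
  expect_lt(abs(rs$mean - 100), 0.1)
  expect_lt(abs(rs$sd - 10), 0.1)
})

test_that("the robust estimator resists bright-outlier contamination", {
  set.seed(20)
  arr <- rnorm(4e4, 100, 10)
  out_idx <- sample(length(arr), 0.05 * length(arr))
  arr[out_idx] <- arr[out_idx] + 100  # +10 sigma outliers
  v <- image_volume(array(arr, c(40, 40, 25)), spacing = 0.65)
  m <- array(TRUE, c(40, 40, 25))
  rob <- reference_stats(v, m, estimator = "robust")
  mom <- reference_stats(v, m, estimator = "moment")
  # analytic contamination oracle: with 5% of mass pushed far above, the MAD
  # is the 52.63rd abs-percentile of the clean part, 1.4826*qnorm(0.7632)*10
  oracle_sd <- 1.4826 * qnorm(0.5 + 0.5 / 0.95 / 2) * 10
  expect_lt(abs(rob$sd - oracle_sd), 0.35)
  expect_lt(rob$sd, 11)       # robust stays close to the clean SD ...
  expect_gt(mom$sd, 20)       # ... while the moment estimator blows up
})

test_that("classification is strict, monotone in k, and empty in the limit", {
  ph <- generate_phantom(lesioned_phantom(seed = 44))
  ref <- reference_stats(ph$stir_t0, ph$marrow_ref_mask)
  maps <- lapply(c(1, 2, 3, 4), function(k)
    classify_edema(ph$stir_t0, ph$marrow_mask, ph$bone_mask, ref, k = k))
  for (i in 1:3) {
    expect_true(all(maps[[i]]$mask$data | !maps[[i + 1]]$mask$data))
  }
  far <- classify_edema(ph$stir_t0, ph$marrow_mask, ph$bone_mask, ref, k = 50)
  expect_equal(sum(far$mask$data), 0)
  expect_error(classify_edema(ph$stir_t0, ph$marrow_mask, ph$bone_mask, ref, k = 0),
               "positive")
  # strict inequality: a voxel exactly at the threshold is excluded
  flat <- image_volume(array(10, c(16, 16, 16)), spacing = 0.65)
  all16 <- array(TRUE, c(16, 16, 16))
  e <- classify_edema(flat, all16, all16, manual_reference_stats(8, 1), k = 2)
  expect_equal(sum(e$mask$data), 0)
})

test_that("a +6 SD lesion interior is fully classified", {
  ph <- generate_phantom(lesioned_phantom(radius_mm = 4, contrast = 6, seed = 50))
  ref <- reference_stats(ph$stir_t0, ph$marrow_ref_mask)
  e <- classify_edema(ph$stir_t0, ph$marrow_mask, ph$bone_mask, ref)
  # erode the truth mask by one voxel along each axis
  tr <- periomri:::mask_array(ph$truth$lesion_mask_t0)
  d <- dim(tr)
  er <- tr
  er[-1, , ] <- er[-1, , ] & tr[-d[1], , ]; er[-d[1], , ] <- er[-d[1], , ] & tr[-1, , ]
  er[, -1, ] <- er[, -1, ] & tr[, -d[2], ]; er[, -d[2], ] <- er[, -d[2], ] & tr[, -1, ]
  er[, , -1] <- er[, , -1] & tr[, , -d[3]]; er[, , -d[3]] <- er[, , -d[3]] & tr[, , -1]
  expect_true(all(e$mask$data[er]))
})

test_that("connected-component filtering removes salt noise but keeps lesions", {
  m <- array(FALSE, c(20, 20, 20))
  m[5:9, 5:9, 5:9] <- TRUE          # 125-voxel blob
  m[15, 15, 15] <- TRUE             # isolated voxel
  m[2, 18, 3] <- TRUE
  lab <- periomri:::label_components_3d(m)
  expect_equal(max(lab), 3)
  expect_equal(sort(tabulate(lab)), c(1, 1, 125))
  kept <- periomri:::drop_small_components(m, 10)
  expect_equal(sum(kept), 125)
})

test_that("change maps conserve volume exactly and validate grids", {
  set.seed(60)
  sp <- 0.65
  mk <- function(arr) {
    structure(list(mask = image_volume(arr, spacing = sp), roi_id = "Q1",
                   timepoint = "t0", threshold_used = 0, k = 2,
                   min_cluster_mm3 = 0), class = "edema_map")
  }
  for (i in 1:10) {
    a <- array(runif(16^3) < 0.3, c(16, 16, 16))
    b <- array(runif(16^3) < 0.3, c(16, 16, 16))
    ch <- change_maps(mk(a), mk(b))$report
    expect_equal(ch$reduction_mm3 + ch$stable_mm3, sum(a) * sp^3)
    expect_equal(ch$new_mm3 + ch$stable_mm3, sum(b) * sp^3)
  }
  a <- array(runif(16^3) < 0.3, c(16, 16, 16))
  same <- change_maps(mk(a), mk(a))$report
  expect_equal(same$reduction_mm3, 0)
  expect_equal(same$new_mm3, 0)
  expect_equal(same$stable_mm3, sum(a) * sp^3)

  e0 <- array(FALSE, c(16, 16, 16)); e0[seq_len(1000)] <- TRUE
  empty <- array(FALSE, c(16, 16, 16))
  ch2 <- change_maps(mk(e0), mk(empty))$report
  expect_equal(ch2$reduction_mm3, 1000 * 0.65^3)  # 274.625
  expect_equal(ch2$new_mm3, 0)

  wrong <- structure(list(mask = image_volume(array(FALSE, c(8, 8, 8)), spacing = sp),
                          roi_id = "Q1", timepoint = "t1", threshold_used = 0,
                          k = 2, min_cluster_mm3 = 0), class = "edema_map")
  expect_error(change_maps(mk(a), wrong), "grids")
})

test_that("the change label map matches the change report exactly", {
  set.seed(61)
  mk <- function(arr) {
    structure(list(mask = image_volume(arr, spacing = 0.65), roi_id = "Q1",
                   timepoint = "t0", threshold_used = 0, k = 2,
                   min_cluster_mm3 = 0), class = "edema_map")
  }
  a <- array(runif(12^3) < 0.25, c(12, 12, 12))
  b <- array(runif(12^3) < 0.25, c(12, 12, 12))
  ch <- change_maps(mk(a), mk(b))
  lm <- render_change_labelmap(mk(a), mk(b))
  expect_equal(sum(lm$data == 1) * 0.65^3, ch$report$reduction_mm3)
  expect_equal(sum(lm$data == 2) * 0.65^3, ch$report$new_mm3)
  expect_equal(sum(lm$data == 3) * 0.65^3, ch$report$stable_mm3)
  expect_true(all(render_change_labelmap(mk(a), mk(a))$data %in% c(0L, 3L)))
  lm2 <- render_change_labelmap(mk(a), mk(array(FALSE, c(12, 12, 12))))
  expect_true(all(lm2$data %in% c(0L, 1L)))
})

test_that("edema depth measures the longest contiguous run along the site ray", {
  # hand-built map: an edema slab spanning 4 voxel centres along z
  arr <- array(FALSE, c(11, 11, 20))
  arr[6, 6, 9:12] <- TRUE
  e <- structure(list(mask = image_volume(arr, spacing = 0.65), roi_id = "Q1",
                      timepoint = "t0", threshold_used = 0, k = 2,
                      min_cluster_mm3 = 0), class = "edema_map")
  site <- list(crest_x = 5 * 0.65, crest_y = 5 * 0.65, crest_z = 19 * 0.65,
               apical_x = 0, apical_y = 0, apical_z = -1)
  ed <- edema_depth(e, site)
  expect_lt(abs(ed - 2.6), 0.65 + 1e-9)
  expect_equal(edema_depth(e, site, rounding = "nearest_mm"), round(ed))
  # no edema anywhere
  none <- e; none$mask$data[] <- FALSE
  expect_equal(edema_depth(none, site), 0)
  # ray missing the grid entirely warns and returns 0
  off <- list(crest_x = -50, crest_y = -50, crest_z = -50,
              apical_x = 0, apical_y = 0, apical_z = -1)
  expect_warning(ed_off <- edema_depth(e, off), "does not intersect")
  expect_equal(ed_off, 0)
  expect_error(edema_depth(e, list(crest_x = 1, crest_y = 1, crest_z = 1,
                                   apical_x = 0, apical_y = 0, apical_z = 0)),
               "non-zero")
})

test_that("tooth-level summary is the maximum over sites, order-invariant", {
  expect_equal(tooth_max_depth(c(0, 0, 0, 0, 0, 0)), 0)
  expect_equal(tooth_max_depth(c(1, 2, 3, 0, 0, 2)), 3)
  set.seed(70)
  v <- runif(6, 0, 8)
  expect_equal(tooth_max_depth(v), tooth_max_depth(sample(v)))
  expect_equal(tooth_max_depth(c(NA, 2, 5)), 5)
  expect_error(tooth_max_depth(numeric(0)), "no site depths")
  expect_error(tooth_max_depth(rep(1, 7)), "at most 6")
})

test_that("subtraction-image route detects a clean shrinking lesion", {
  cfg0 <- phantom_config(grid_shape = c(40, 40, 40), seed = 1)
  g <- periomri:::phantom_geometry(cfg0)
  ctr <- (g$marrow_lo_mm + g$marrow_hi_mm) / 2
  cfg <- phantom_config(grid_shape = c(40, 40, 40), noise_sd = 0,
                        lesions_t0 = list(lesion(ctr, 5, 6)),
                        lesions_t1 = list(lesion(ctr, 3.5, 6)), seed = 1)
  ph <- generate_phantom(cfg)
  ref <- manual_reference_stats(100, 10)
  ch <- subtraction_change_maps(ph$stir_t0, ph$stir_t1, ph$marrow_mask,
                                ph$bone_mask, ref, ref, roi_id = "all")
  shell <- 4 / 3 * pi * (5^3 - 3.5^3)
  expect_lt(abs(ch$report$reduction_mm3 - shell), 0.15 * shell)
  expect_lt(ch$report$new_mm3, 0.02 * shell)
})

test_that("site CSV round trip preserves the table", {
  ph <- generate_phantom(tiny_phantom_config(seed = 2))
  f <- tempfile(fileext = ".csv")
  write_sites_csv(ph$sites, f)
  back <- read_sites_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(ph$sites), tolerance = 1e-12)
  unlink(f)
})
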