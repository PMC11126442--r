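#' Configure an end-to-end pipeline run
#'
#' A run either simulates its inputs (phantom and/or clinical configs) or
#' consumes real files (volumes, masks, site definitions, site-record CSV);
#' at least one input source must be present. Simulated stages come first,
#' then registration of the follow-up scan into the baseline frame, per-
#' quadrant classification and change-map volumetry, per-site depth
#' measurement, and the clinical/imaging summary tables.
#'
#' @param phantom optional [phantom_config()].
#' @param clinical optional [clinical_sim_config()].
#' @param site_records optional site-record tibble (alternative to
#'   `clinical`).
#' @param k threshold multiplier for edema classification (default 2).
#' @param min_cluster_mm3 minimum-cluster filter for classification
#'   (default 0 = off).
#' @param register logical; estimate and apply the rigid alignment of the
#'   follow-up scan (on by default; identity is used when off).
#' @param register_opts a [register_options()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in the manifest.
#' @return A validated `run_config`.
#' @export
run_config <- function(phantom = NULL, clinical = NULL, site_records = NULL,
                       k = 2, min_cluster_mm3 = 0,
                       register = TRUE, register_opts = register_options(),
                       out_dir = tempfile("periomri_run_"), seed = 1L) {
  if (is.null(phantom) && is.null(clinical) && is.null(site_records)) {
    abort("a run needs at least one input: `phantom`, `clinical` or `site_records`.")
  }
  if (k <= 0) abort("`k` must be positive.")
  structure(
    list(phantom = phantom, clinical = clinical, site_records = site_records,
         k = k, min_cluster_mm3 = min_cluster_mm3, register = register,
         register_opts = register_opts, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

stage_fail <- function(stage, e, path = NULL) {
  abort(sprintf("pipeline stage '%s' failed%s: %s", stage,
                if (is.null(path)) "" else sprintf(" (input %s)", path),
                conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages and writes every artifact under
#' `config$out_dir`: NIfTI volumes and label maps, per-quadrant change
#' reports (JSON + CSV), per-site depth tables, the clinical and imaging
#' summary tables, and a run manifest with input checksums and per-stage
#' timings. Deterministic stages reproduce identical checksums on re-run
#' with the same config.
#'
#' @param config a [run_config()].
#' @return A `run_manifest`: tool version, config hash, artifact paths and
#'   md5 checksums, per-stage timings (seconds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  artifacts <- character(0)
  timings <- numeric(0)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) stage_fail(stage, e))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  imaging_report <- NULL
  if (!is.null(config$phantom)) {
    ph <- tick("simulate_phantom", generate_phantom(config$phantom))
    tick("write_volumes", {
      for (nm in c("stir_t0", "stir_t1", "t1bone_t0", "t1bone_t1")) {
        artifacts <- c(artifacts, write_volume(ph[[nm]], out(paste0(nm, ".nii.gz"))))
      }
      artifacts <- c(artifacts,
                     write_volume(ph$marrow_ref_mask, out("marrow_ref_mask.nii.gz"), mask = TRUE),
                     write_volume(ph$bone_mask, out("bone_mask.nii.gz"), mask = TRUE),
                     write_sites_csv(ph$sites, out("sites.csv")))
      artifacts
    })
    artifacts <- unique(artifacts)

    reg <- tick("register", {
      if (config$register && !is_identity_transform(config$phantom$true_transform)) {
        estimate_rigid(ph$stir_t0, ph$stir_t1, config$register_opts)
      } else {
        list(transform = rigid_transform(), converged = TRUE)
      }
    })
    artifacts <- c(artifacts,
                   write_transform_json(reg$transform, out("transform.json")))
    stir_t1_reg <- resample_volume(ph$stir_t1, reg$transform, "trilinear",
                                   fill = 0)

    quant <- tick("quantify", {
      ref0 <- reference_stats(ph$stir_t0, ph$marrow_ref_mask)
      ref1 <- reference_stats(stir_t1_reg, ph$marrow_ref_mask)
      reports <- list()
      for (q in names(ph$roi_masks)) {
        e0 <- classify_edema(ph$stir_t0, ph$roi_masks[[q]], ph$bone_mask,
                             ref0, k = config$k,
                             min_cluster_mm3 = config$min_cluster_mm3,
                             roi_id = q, timepoint = "t0")
        e1 <- classify_edema(stir_t1_reg, ph$roi_masks[[q]], ph$bone_mask,
                             ref1, k = config$k,
                             min_cluster_mm3 = config$min_cluster_mm3,
                             roi_id = q, timepoint = "t1")
        ch <- change_maps(e0, e1)
        lm <- render_change_labelmap(e0, e1)
        artifacts <- c(artifacts,
                       write_volume(lm, out(sprintf("change_labels_%s.nii.gz", q)),
                                    mask = TRUE))
        reports[[q]] <- list(change = ch, e0 = e0, e1 = e1)
      }
      reports
    })
    imaging_report <- dplyr::bind_rows(purrr::map(quant, ~ .x$change$report))
    artifacts <- c(artifacts, out("change_reports.csv"))
    write.csv(imaging_report, out("change_reports.csv"), row.names = FALSE)

    depths <- tick("site_depths", {
      roi_all <- Reduce(`|`, purrr::map(ph$roi_masks, ~ .x$data))
      full0 <- classify_edema(ph$stir_t0, image_volume(roi_all, ph$stir_t0$spacing),
                              ph$bone_mask, reference_stats(ph$stir_t0, ph$marrow_ref_mask),
                              k = config$k, min_cluster_mm3 = config$min_cluster_mm3,
                              timepoint = "t0")
      full1 <- classify_edema(stir_t1_reg, image_volume(roi_all, ph$stir_t0$spacing),
                              ph$bone_mask, reference_stats(stir_t1_reg, ph$marrow_ref_mask),
                              k = config$k, min_cluster_mm3 = config$min_cluster_mm3,
                              timepoint = "t1")
      dplyr::bind_rows(
        dplyr::mutate(measure_site_depths(full0, ph$sites), timepoint = "t0"),
        dplyr::mutate(measure_site_depths(full1, ph$sites), timepoint = "t1")
      )
    })
    artifacts <- c(artifacts, out("site_depths.csv"))
    write.csv(depths, out("site_depths.csv"), row.names = FALSE)

    jsonlite::write_json(
      list(k = config$k, min_cluster_mm3 = config$min_cluster_mm3,
           quadrants = imaging_report,
           registration_converged = reg$converged),
      out("imaging_report.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    artifacts <- c(artifacts, out("imaging_report.json"))
  }

  records <- config$site_records
  if (!is.null(config$clinical)) {
    records <- tick("simulate_sites", generate_site_table(config$clinical))
  }
  if (!is.null(records)) {
    tabs <- tick("stats", list(table2 = build_table2(records),
                               table3 = build_table3(records)))
    artifacts <- c(artifacts,
                   write_site_records_csv(records, out("site_records.csv")),
                   write_stat_table(tabs$table2, out("table_clinical.csv")),
                   out("table_clinical.json"),
                   write_stat_table(tabs$table3, out("table_edema.csv")),
                   out("table_edema.json"))
  }

  cfg_strip <- config[setdiff(names(config), "out_dir")]
  manifest <- structure(
    list(
      tool = sprintf("periomri %s", as.character(utils::packageVersion("periomri"))),
      seed = config$seed,
      config_hash = unname(tools::md5sum(local({
        f <- tempfile(); saveRDS(cfg_strip, f, version = 2); f
      }))),
      stage_timings_s = as.list(timings),
      artifacts = tibble(
        path = basename(unique(artifacts)),
        md5 = unname(tools::md5sum(unique(artifacts)))
      )
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(tool = manifest$tool, seed = manifest$seed,
         config_hash = manifest$config_hash,
         stage_timings_s = manifest$stage_timings_s,
         artifacts = manifest$artifacts),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s, %d artifacts\n", x$tool, nrow(x$artifacts)))
  print(x$artifacts)
  invisible(x)
}

#' Change-class label map
#'
#' Collapses a pair of co-registered edema maps into one label volume for
#' visualization and export: 0 = no edema, 1 = reduction (baseline only),
#' 2 = new (follow-up only), 3 = stable (both). Label counts match the
#' change report exactly by construction.
#'
#' @param e0,e1_registered co-registered `edema_map`s (see [change_maps()]).
#' @return An `image_volume` with integer labels 0-3.
#' @export
render_change_labelmap <- function(e0, e1_registered) {
  stopifnot(inherits(e0, "edema_map"), inherits(e1_registered, "edema_map"))
  if (!same_grid(e0$mask, e1_registered$mask)) {
    abort("edema maps are on different grids; register before labelling.")
  }
  m0 <- e0$mask$data; m1 <- e1_registered$mask$data
  lab <- array(0L, dim(m0))
  lab[m0 & !m1] <- 1L
  lab[!m0 & m1] <- 2L
  lab[m0 & m1] <- 3L
  image_volume(lab, spacing = e0$mask$spacing, origin = e0$mask$origin)
}
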