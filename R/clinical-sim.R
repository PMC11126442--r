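#' Configure the clinical site simulator
#'
#' Simulates paired (baseline and 3-month follow-up) site records — probing
#' pocket depth (PPD, integer mm), bleeding on probing (BOP, binary) and
#' edema depth (ED, mm) — at the six probing sites of each molar tooth, with
#' the marginal structure of a treated periodontitis cohort: at baseline
#' roughly 52/33/15% of sites in the PPD <= 3 / 4-5 / >= 6 mm bands
#' (shifting to about 57/31/12% after treatment), about 45% of sites
#' bleeding on probing falling to under 30%, and marrow edema at about 35%
#' of sites falling to about 24%, with ED medians near 2 mm before and 1 mm
#' after treatment.
#'
#' Category probabilities refer to the four clinical strata
#' (PPD <= 3 mm without BOP, PPD <= 3 mm with BOP, PPD 4-5 mm, PPD >= 6 mm).
#' Timepoints are drawn from their own category distributions (sites migrate
#' between strata under treatment); edema at follow-up is linked to baseline
#' edema through a persistence probability so the pre/post ED comparison is
#' genuinely paired.
#'
#' @param n_patients number of patients (default 35, a desk-scale cohort).
#' @param teeth_per_patient molars per patient (at most 8).
#' @param sites_per_tooth fixed at 6 probing sites.
#' @param n_sites optional total-site cap: generation is truncated to the
#'   first `n_sites` sites, for calibration runs at an exact n.
#' @param category_probs_t0,category_probs_t1 probabilities over the four
#'   strata; must each sum to 1 (tolerance 1e-9).
#' @param ppd_dists list of 4 named probability vectors giving the integer
#'   PPD distribution within each stratum (names are mm values, respecting
#'   the stratum bounds).
#' @param bop_prob_by_category_t0,bop_prob_by_category_t1 BOP probability
#'   per stratum and visit; the first two strata are fixed at 0 and 1 by
#'   definition.
#' @param edema_prob_by_category_t0 baseline probability of marrow edema per
#'   stratum.
#' @param edema_persist_prob probability a baseline-edema site still shows
#'   edema at follow-up.
#' @param edema_new_prob probability an edema-free site shows new edema at
#'   follow-up.
#' @param ed_dists_t0,ed_dists_t1 list of 4 named probability vectors for ED
#'   (mm, >= 1) given edema, per baseline stratum and visit.
#' @param seed integer seed.
#' @return A validated `clinical_sim_config` list.
#' @export
clinical_sim_config <- function(
    n_patients = 35,
    teeth_per_patient = 4,
    sites_per_tooth = 6,
    n_sites = NULL,
    category_probs_t0 = c(0.342, 0.178, 0.33, 0.15),
    category_probs_t1 = c(0.4275, 0.1425, 0.31, 0.12),
    ppd_dists = list(
      c("1" = 0.25, "2" = 0.15, "3" = 0.60),
      c("1" = 0.10, "2" = 0.10, "3" = 0.80),
      c("4" = 0.70, "5" = 0.30),
      c("6" = 0.60, "7" = 0.25, "8" = 0.10, "9" = 0.05)
    ),
    bop_prob_by_category_t0 = c(0, 1, 0.50, 0.70),
    bop_prob_by_category_t1 = c(0, 1, 0.35, 0.25),
    edema_prob_by_category_t0 = c(0.12, 0.25, 0.40, 0.85),
    edema_persist_prob = 0.55,
    edema_new_prob = 0.085,
    ed_dists_t0 = list(
      c("1" = 0.30, "2" = 0.30, "3" = 0.25, "4" = 0.10, "5" = 0.05),
      c("1" = 0.50, "2" = 0.15, "3" = 0.20, "4" = 0.10, "5" = 0.05),
      c("1" = 0.55, "2" = 0.25, "3" = 0.12, "4" = 0.05, "5" = 0.03),
      c("1" = 0.20, "2" = 0.32, "3" = 0.13, "4" = 0.08, "5" = 0.17, "6" = 0.10)
    ),
    ed_dists_t1 = list(
      c("1" = 0.35, "2" = 0.30, "3" = 0.20, "4" = 0.10, "5" = 0.05),
      c("1" = 0.45, "2" = 0.20, "3" = 0.20, "4" = 0.10, "5" = 0.05),
      c("1" = 0.60, "2" = 0.25, "3" = 0.10, "4" = 0.05),
      c("1" = 0.40, "2" = 0.25, "3" = 0.20, "4" = 0.10, "5" = 0.05)
    ),
    seed = 1L) {
  check_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("%s must sum to 1 (got %.12g).", what, sum(p)))
    }
    if (any(p < 0)) abort(sprintf("%s must be non-negative.", what))
  }
  check_probs(category_probs_t0, "category_probs_t0")
  check_probs(category_probs_t1, "category_probs_t1")
  for (i in 1:4) {
    check_probs(ppd_dists[[i]], sprintf("ppd_dists[[%d]]", i))
    check_probs(ed_dists_t0[[i]], sprintf("ed_dists_t0[[%d]]", i))
    check_probs(ed_dists_t1[[i]], sprintf("ed_dists_t1[[%d]]", i))
  }
  ppd_vals <- lapply(ppd_dists, function(p) as.numeric(names(p)))
  bounds_ok <- all(ppd_vals[[1]] <= 3) && all(ppd_vals[[2]] <= 3) &&
    all(ppd_vals[[3]] >= 4 & ppd_vals[[3]] <= 5) && all(ppd_vals[[4]] >= 6)
  if (!bounds_ok) abort("`ppd_dists` values must respect the stratum PPD bounds.")
  if (sites_per_tooth != 6L) abort("`sites_per_tooth` is fixed at 6.")
  if (teeth_per_patient > 8L) abort("at most 8 molars per patient.")
  structure(
    list(n_patients = as.integer(n_patients),
         teeth_per_patient = as.integer(teeth_per_patient),
         sites_per_tooth = 6L, n_sites = n_sites,
         category_probs_t0 = category_probs_t0,
         category_probs_t1 = category_probs_t1,
         ppd_dists = ppd_dists,
         bop_prob_by_category_t0 = bop_prob_by_category_t0,
         bop_prob_by_category_t1 = bop_prob_by_category_t1,
         edema_prob_by_category_t0 = edema_prob_by_category_t0,
         edema_persist_prob = edema_persist_prob,
         edema_new_prob = edema_new_prob,
         ed_dists_t0 = ed_dists_t0, ed_dists_t1 = ed_dists_t1,
         seed = as.integer(seed)),
    class = "clinical_sim_config"
  )
}

sample_from <- function(dist, n) {
  vals <- as.numeric(names(dist))
  if (n == 0) return(numeric(0))
  vals[sample.int(length(vals), n, replace = TRUE, prob = dist)]
}

#' Simulate a paired site-record table
#'
#' Draws one record per site per timepoint; site identity
#' (patient, tooth, site position) is stable across timepoints. Empirical
#' stratum frequencies converge to the configured probabilities as the
#' number of sites grows.
#'
#' @param config a [clinical_sim_config()].
#' @return A tibble with columns `patient_id`, `tooth_id` (FDI),
#'   `site_position`, `timepoint` (`"t0"`/`"t1"`), `ppd_mm`, `bop`,
#'   `ed_mm`, `edema_present`.
#' @examples
#' sites <- generate_site_table(clinical_sim_config(n_patients = 2, seed = 42))
#' dplyr::count(sites, timepoint)
#' @export
generate_site_table <- function(config) {
  stopifnot(inherits(config, "clinical_sim_config"))
  withr::with_seed(config$seed, generate_site_table_impl(config))
}

generate_site_table_impl <- function(cfg) {
  positions <- c("buccal_anterior", "buccal_mid", "buccal_posterior",
                 "lingual_anterior", "lingual_mid", "lingual_posterior")
  fdi <- c("16", "17", "26", "27", "36", "37", "46", "47")
  if (cfg$n_patients == 0L) {
    return(tibble(patient_id = character(), tooth_id = character(),
                  site_position = character(), timepoint = character(),
                  ppd_mm = integer(), bop = integer(), ed_mm = numeric(),
                  edema_present = integer()))
  }
  base <- tidyr::expand_grid(
    patient_id = sprintf("P%03d", seq_len(cfg$n_patients)),
    tooth_id = fdi[seq_len(cfg$teeth_per_patient)],
    site_position = positions
  )
  if (!is.null(cfg$n_sites)) {
    if (cfg$n_sites > nrow(base)) {
      abort(sprintf("n_sites = %d exceeds the %d sites generated by the cohort.",
                    cfg$n_sites, nrow(base)))
    }
    base <- base[seq_len(cfg$n_sites), ]
  }
  n <- nrow(base)

  draw_visit <- function(cat_probs, bop_probs) {
    cat <- sample.int(4L, n, replace = TRUE, prob = cat_probs)
    ppd <- integer(n); bop <- integer(n)
    for (ci in 1:4) {
      idx <- which(cat == ci)
      ppd[idx] <- as.integer(sample_from(cfg$ppd_dists[[ci]], length(idx)))
      p_bop <- c(0, 1, bop_probs[3], bop_probs[4])[ci]
      bop[idx] <- as.integer(runif(length(idx)) < p_bop)
    }
    list(cat = cat, ppd = ppd, bop = bop)
  }
  v0 <- draw_visit(cfg$category_probs_t0, cfg$bop_prob_by_category_t0)
  v1 <- draw_visit(cfg$category_probs_t1, cfg$bop_prob_by_category_t1)

  present0 <- runif(n) < cfg$edema_prob_by_category_t0[v0$cat]
  present1 <- ifelse(present0, runif(n) < cfg$edema_persist_prob,
                     runif(n) < cfg$edema_new_prob)
  ed0 <- numeric(n); ed1 <- numeric(n)
  for (ci in 1:4) {
    i0 <- which(present0 & v0$cat == ci)
    ed0[i0] <- sample_from(cfg$ed_dists_t0[[ci]], length(i0))
    i1 <- which(present1 & v0$cat == ci)
    ed1[i1] <- sample_from(cfg$ed_dists_t1[[ci]], length(i1))
  }

  dplyr::bind_rows(
    dplyr::mutate(base, timepoint = "t0", ppd_mm = v0$ppd, bop = v0$bop,
                  ed_mm = ed0, edema_present = as.integer(present0)),
    dplyr::mutate(base, timepoint = "t1", ppd_mm = v1$ppd, bop = v1$bop,
                  ed_mm = ed1, edema_present = as.integer(present1))
  )
}

#' Read and write site-record tables
#'
#' Plain-CSV I/O for the site-record layout produced by
#' [generate_site_table()].
#'
#' @param path CSV path.
#' @export
read_site_records_csv <- function(path) {
  as_tibble(read.csv(path, colClasses = c(tooth_id = "character",
                                          patient_id = "character")))
}

#' @rdname read_site_records_csv
#' @param records a site-record tibble.
#' @export
write_site_records_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
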