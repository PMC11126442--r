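#' Clinical site categories
#'
#' Assigns each site to one of the four clinical strata used for
#' stratified reporting: `PPD<=3 noBOP`, `PPD<=3 BOP`, `PPD4-5` and
#' `PPD>=6`. The bleeding split applies only to shallow (<= 3 mm) pockets;
#' deeper pockets are categorized by depth alone. Stratum membership for
#' before/after comparisons is conventionally taken at baseline.
#'
#' @param ppd_mm integer probing pocket depths (mm).
#' @param bop binary bleeding-on-probing indicators.
#' @return A factor with the four stratum levels, same length as `ppd_mm`.
#' @examples
#' categorize_ppd(c(3, 4, 6), c(0, 1, 0))
#' @export
categorize_ppd <- function(ppd_mm, bop) {
  if (any(ppd_mm < 0, na.rm = TRUE)) abort("PPD must be non-negative.")
  out <- dplyr::case_when(
    ppd_mm <= 3 & bop == 0 ~ "PPD<=3 noBOP",
    ppd_mm <= 3 & bop == 1 ~ "PPD<=3 BOP",
    ppd_mm <= 5 ~ "PPD4-5",
    TRUE ~ "PPD>=6"
  )
  factor(out, levels = site_category_levels())
}

#' @rdname categorize_ppd
#' @export
site_category_levels <- function() {
  c("PPD<=3 noBOP", "PPD<=3 BOP", "PPD4-5", "PPD>=6")
}

#' @rdname categorize_ppd
#' @param records a site-record tibble (see [generate_site_table()]).
#' @return `categorize_sites()`: the records with a `category` column
#'   computed per row from that row's PPD/BOP, and a `category_t0` column
#'   carrying each site's baseline stratum across both timepoints.
#' @export
categorize_sites <- function(records) {
  records <- dplyr::mutate(records,
                           category = categorize_ppd(.data$ppd_mm, .data$bop))
  base <- dplyr::filter(records, .data$timepoint == "t0")
  base <- dplyr::select(base, "patient_id", "tooth_id", "site_position",
                        category_t0 = "category")
  dplyr::left_join(records, base,
                   by = c("patient_id", "tooth_id", "site_position"))
}

round_half_up <- function(x) floor(x + 0.5)

#' Integer percentage with explicit denominator
#'
#' The rendering convention of the summary tables: percentages are rounded
#' half-up to the nearest integer, e.g. `percent_of(591, 1140)` is 52.
#'
#' @param count,denominator non-negative counts, `denominator > 0`.
#' @return Integer percent.
#' @export
percent_of <- function(count, denominator) {
  if (any(denominator <= 0)) abort("`denominator` must be positive.")
  round_half_up(100 * count / denominator)
}

site_key <- function(records) {
  paste(records$patient_id, records$tooth_id, records$site_position, sep = "|")
}

pair_records <- function(records) {
  t0 <- dplyr::filter(records, .data$timepoint == "t0")
  t1 <- dplyr::filter(records, .data$timepoint == "t1")
  k0 <- site_key(t0); k1 <- site_key(t1)
  orphans <- c(setdiff(k0, k1), setdiff(k1, k0))
  if (length(orphans)) {
    abort(paste0("unmatched site keys between timepoints: ",
                 paste(head(orphans, 5), collapse = "; "),
                 if (length(orphans) > 5) sprintf(" (and %d more)", length(orphans) - 5)))
  }
  if (anyDuplicated(k0) || anyDuplicated(k1)) {
    abort("duplicate (patient, tooth, site, timepoint) records.")
  }
  t1 <- t1[match(k0, k1), ]
  list(t0 = t0, t1 = t1)
}

stat_table_row <- function(section, stratum, n_t0, n_t1, stat_type,
                           median_t0 = NA_real_, q1_t0 = NA_real_, q3_t0 = NA_real_,
                           median_t1 = NA_real_, q1_t1 = NA_real_, q3_t1 = NA_real_,
                           count_t0 = NA_real_, pct_t0 = NA_real_,
                           count_t1 = NA_real_, pct_t1 = NA_real_,
                           denom_t0 = NA_real_, denom_t1 = NA_real_,
                           summary_t0 = NA_character_, summary_t1 = NA_character_,
                           test = NA_character_, p_value = NA_real_,
                           empty = FALSE) {
  tibble(section = section, stratum = stratum, n_t0 = n_t0, n_t1 = n_t1,
         stat_type = stat_type,
         median_t0 = median_t0, q1_t0 = q1_t0, q3_t0 = q3_t0,
         median_t1 = median_t1, q1_t1 = q1_t1, q3_t1 = q3_t1,
         count_t0 = count_t0, pct_t0 = pct_t0,
         count_t1 = count_t1, pct_t1 = pct_t1,
         denom_t0 = denom_t0, denom_t1 = denom_t1,
         summary_t0 = summary_t0, summary_t1 = summary_t1,
         test = test, p_value = p_value, empty = empty)
}

median_row <- function(section, stratum, x0, x1, unit = " mm") {
  if (!length(x0)) {
    return(stat_table_row(section, stratum, 0, 0, "median_iqr", empty = TRUE))
  }
  m0 <- median_iqr(x0); m1 <- median_iqr(x1)
  p <- if (length(x0) >= 5) wilcoxon_paired(x0, x1)$p_value else NA_real_
  stat_table_row(
    section, stratum, length(x0), length(x1), "median_iqr",
    median_t0 = m0["median"], q1_t0 = m0["q1"], q3_t0 = m0["q3"],
    median_t1 = m1["median"], q1_t1 = m1["q1"], q3_t1 = m1["q3"],
    summary_t0 = format_median_iqr(x0, unit), summary_t1 = format_median_iqr(x1, unit),
    test = "Wilcoxon signed-rank (paired)", p_value = p
  )
}

count_row <- function(section, stratum, c0, d0, c1, d1, test, p) {
  stat_table_row(
    section, stratum, c0, c1, "count_pct",
    count_t0 = c0, pct_t0 = percent_of(c0, d0),
    count_t1 = c1, pct_t1 = percent_of(c1, d1),
    denom_t0 = d0, denom_t1 = d1,
    summary_t0 = sprintf("%d (%d%%)", c0, percent_of(c0, d0)),
    summary_t1 = sprintf("%d (%d%%)", c1, percent_of(c1, d1)),
    test = test, p_value = p
  )
}

new_stat_table <- function(df, title) {
  structure(df, class = c("stat_table", class(df)),
            title = title,
            percentile_convention = "linear interpolation (quantile type 7)",
            percent_rounding = "half-up to integer")
}

#' @export
print.stat_table <- function(x, ...) {
  cat(sprintf("<stat_table> %s\n", attr(x, "title")))
  cols <- c("section", "stratum", "n_t0", "summary_t0", "summary_t1",
            "test", "p_value")
  print(as_tibble(x)[, cols], n = Inf)
  invisible(x)
}

#' @export
tidy.stat_table <- function(x, ...) as_tibble(x)

#' @export
glance.stat_table <- function(x, ...) {
  tibble(
    title = attr(x, "title"),
    n_rows = nrow(x),
    n_sites = max(x$denom_t0, na.rm = TRUE),
    min_p = min(x$p_value, na.rm = TRUE),
    percentile_convention = attr(x, "percentile_convention")
  )
}

#' Site-level clinical summary table (probing depth and bleeding)
#'
#' Builds the standard pre/post clinical table: PPD median [IQR] at both
#' visits with the paired Wilcoxon p-value, overall and within each baseline
#' stratum; category counts per visit (PPD bands <= 3 / 4-5 / >= 6 mm,
#' categories re-assigned at each visit from that visit's PPD) compared with
#' an unpaired Pearson chi-square (no Yates on the 2x3 band table); and a
#' bleeding-on-probing frequency row compared with a Yates-corrected 2x2
#' chi-square. Percentages carry explicit denominators.
#'
#' @param records a paired site-record tibble (both timepoints, matching
#'   site keys; an error lists any orphans).
#' @return A `stat_table` tibble; see [tidy()]/[glance()] methods.
#' @export
build_table2 <- function(records) {
  pr <- pair_records(categorize_sites(records))
  t0 <- pr$t0; t1 <- pr$t1
  rows <- list(median_row("ppd", sprintf("all sites (n = %d)", nrow(t0)),
                          t0$ppd_mm, t1$ppd_mm))
  for (lev in site_category_levels()) {
    i <- which(t0$category == lev)
    rows[[length(rows) + 1]] <-
      median_row("ppd", sprintf("%s (n = %d)", lev, length(i)),
                 t0$ppd_mm[i], t1$ppd_mm[i])
  }
  band <- function(p) cut(p, c(-Inf, 3, 5, Inf), labels = c("PPD<=3", "PPD4-5", "PPD>=6"))
  b0 <- table(band(t0$ppd_mm)); b1 <- table(band(t1$ppd_mm))
  p_band <- chi_square(rbind(as.numeric(b0), as.numeric(b1)), yates = "auto")$p_value
  for (bn in names(b0)) {
    rows[[length(rows) + 1]] <-
      count_row("category_counts", bn, as.numeric(b0[bn]), nrow(t0),
                as.numeric(b1[bn]), nrow(t1), "Pearson chi-square", p_band)
  }
  bop0 <- sum(t0$bop); bop1 <- sum(t1$bop)
  p_bop <- chi_square(rbind(c(bop0, nrow(t0) - bop0), c(bop1, nrow(t1) - bop1)),
                      yates = "auto")$p_value
  rows[[length(rows) + 1]] <-
    count_row("bop", "with BOP", bop0, nrow(t0), bop1, nrow(t1),
              "Pearson chi-square (Yates)", p_bop)
  new_stat_table(dplyr::bind_rows(rows),
                 "Clinical parameters at single sites before and after treatment")
}

#' Site-level edema summary table
#'
#' Builds the imaging counterpart of [build_table2()]: the count and
#' percentage of edema-affected sites at each visit (unpaired Yates 2x2
#' chi-square), and — among sites with edema at baseline — the edema depth
#' median [IQR] at both visits with the paired Wilcoxon p-value, overall and
#' within each baseline clinical stratum. With no baseline edema at all, the
#' depth rows are flagged `empty`.
#'
#' @inheritParams build_table2
#' @return A `stat_table` tibble.
#' @export
build_table3 <- function(records) {
  pr <- pair_records(categorize_sites(records))
  t0 <- pr$t0; t1 <- pr$t1
  n <- nrow(t0)
  a0 <- sum(t0$edema_present); a1 <- sum(t1$edema_present)
  p_aff <- if (a0 + a1 == 0 || (n - a0) + (n - a1) == 0) {
    NA_real_  # no affected (or no unaffected) sites at either visit
  } else {
    chi_square(rbind(c(a0, n - a0), c(a1, n - a1)), yates = "auto")$p_value
  }
  rows <- list(count_row("affected_sites", sprintf("All sites (n = %d)", n),
                         a0, n, a1, n, "Pearson chi-square (Yates)", p_aff))
  init <- which(t0$edema_present == 1)
  rows[[length(rows) + 1]] <-
    median_row("ed", sprintf("All sites with initial edema (n = %d)", length(init)),
               t0$ed_mm[init], t1$ed_mm[init])
  for (lev in site_category_levels()) {
    i <- intersect(init, which(t0$category == lev))
    rows[[length(rows) + 1]] <-
      median_row("ed", sprintf("%s (n = %d)", lev, length(i)),
                 t0$ed_mm[i], t1$ed_mm[i])
  }
  new_stat_table(dplyr::bind_rows(rows),
                 "Edema extent at single sites before and after treatment")
}

#' Write a stat table with its conventions
#'
#' Writes the full table as CSV and a JSON sidecar with the metadata
#' (title, percentile and rounding conventions), so outputs are
#' self-describing.
#'
#' @param x a `stat_table`.
#' @param path CSV output path; the JSON sidecar gets extension `.json`.
#' @export
write_stat_table <- function(x, path) {
  write.csv(as_tibble(x), path, row.names = FALSE)
  meta <- list(title = attr(x, "title"),
               percentile_convention = attr(x, "percentile_convention"),
               percent_rounding = attr(x, "percent_rounding"))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
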