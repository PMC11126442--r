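test_that("site categorization follows the stratum boundaries", {
  expect_equal(as.character(categorize_ppd(3, 0)), "PPD<=3 noBOP")
  expect_equal(as.character(categorize_ppd(3, 1)), "PPD<=3 BOP")
  # bleeding is ignored above 3 mm
  expect_equal(as.character(categorize_ppd(4, 1)), "PPD4-5")
  expect_equal(as.character(categorize_ppd(5, 0)), "PPD4-5")
  expect_equal(as.character(categorize_ppd(6, 0)), "PPD>=6")
  expect_error(categorize_ppd(-1, 0), "non-negative")
})

test_that("categories partition any record set", {
  tab <- generate_site_table(clinical_sim_config(n_patients = 10, seed = 2))
  cats <- categorize_sites(tab)
  expect_equal(sum(table(cats$category)), nrow(tab))
  expect_false(any(is.na(cats$category)))
})

test_that("percent rendering rounds half-up with explicit denominators", {
  expect_equal(percent_of(591, 1140), 52)
  expect_equal(percent_of(631, 1110), 57)
  expect_equal(percent_of(321, 922), 35)
  expect_equal(percent_of(1, 8), 13)  # 12.5 rounds up
  expect_error(percent_of(1, 0), "positive")
})

make_records <- function(n = 40, seed = 123) {
  generate_site_table(clinical_sim_config(n_patients = n, seed = seed))
}

test_that("the clinical table has the expected strata, counts and conventions", {
  rec <- make_records(30)
  t2 <- build_table2(rec)
  expect_s3_class(t2, "stat_table")
  med <- subset(as.data.frame(t2), stat_type == "median_iqr")
  expect_equal(nrow(med), 5)  # all sites + 4 strata
  expect_equal(med$n_t0[1], nrow(rec) / 2)
  expect_equal(sum(med$n_t0[-1]), med$n_t0[1])  # strata partition the sites
  cnt <- subset(as.data.frame(t2), stat_type == "count_pct")
  expect_equal(sum(cnt$count_t0[cnt$section == "category_counts"]), med$n_t0[1])
  expect_true(all(cnt$denom_t0 == med$n_t0[1]))
  expect_equal(attr(t2, "percentile_convention"),
               "linear interpolation (quantile type 7)")
})

test_that("orphan and duplicate site keys are rejected", {
  rec <- make_records(5)
  expect_error(build_table2(rec[-1, ]), "unmatched site keys")
  expect_error(build_table2(rbind(rec, rec[1, ])), "duplicate|unmatched")
})

test_that("doubling every record leaves percentages unchanged and doubles n", {
  rec <- make_records(15)
  rec2 <- rec
  rec2$patient_id <- paste0(rec2$patient_id, "_copy")
  both <- rbind(rec, rec2)
  a <- as.data.frame(build_table2(rec))
  b <- as.data.frame(build_table2(both))
  ca <- subset(a, stat_type == "count_pct")
  cb <- subset(b, stat_type == "count_pct")
  expect_equal(cb$pct_t0, ca$pct_t0)
  expect_equal(cb$count_t0, 2 * ca$count_t0)
  mb <- subset(b, stat_type == "median_iqr")
  ma <- subset(a, stat_type == "median_iqr")
  expect_equal(mb$median_t0, ma$median_t0)
})

test_that("the edema table counts affected sites and summarizes depths", {
  rec <- make_records(30)
  t3 <- build_table3(rec)
  aff <- subset(as.data.frame(t3), section == "affected_sites")
  t0 <- subset(rec, timepoint == "t0")
  expect_equal(aff$count_t0, sum(t0$edema_present))
  expect_equal(aff$denom_t0, nrow(t0))
  ed <- subset(as.data.frame(t3), section == "ed")
  expect_equal(ed$n_t0[1], sum(t0$edema_present))
})

test_that("a cohort without edema yields zero counts and empty-flagged depth rows", {
  rec <- make_records(5)
  rec$ed_mm <- 0
  rec$edema_present <- 0L
  t3 <- as.data.frame(build_table3(rec))
  expect_equal(subset(t3, section == "affected_sites")$count_t0, 0)
  expect_true(all(subset(t3, section == "ed")$empty))
})

test_that("stat tables expose tidy(), glance() and autoplot()", {
  rec <- make_records(10)
  t2 <- build_table2(rec)
  expect_s3_class(tidy(t2), "tbl_df")
  g <- glance(t2)
  expect_equal(g$n_sites, nrow(rec) / 2)
  expect_s3_class(autoplot(t2), "ggplot")
  f <- tempfile(fileext = ".csv")
  write_stat_table(t2, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.csv$", ".json", f)))
  unlink(c(f, sub("\\.csv$", ".json", f)))
})
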