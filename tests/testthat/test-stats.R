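test_that("median_iqr follows the linear-interpolation convention", {
  expect_equal(as.numeric(median_iqr(3)), c(3, 3, 3))
  expect_equal(as.numeric(median_iqr(c(1, 2, 3, 4))), c(2.5, 1.75, 3.25))
  set.seed(1)
  x <- rnorm(37)
  expect_equal(median_iqr(x), median_iqr(sample(x)))
  expect_error(median_iqr(numeric(0)), "at least one")
})

test_that("paired Wilcoxon handles degenerate and exact cases", {
  x <- c(3, 4, 5, 2, 6)
  r <- wilcoxon_paired(x, x)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_error(wilcoxon_paired(1:4, 2:5), "at least 5")
  expect_error(wilcoxon_paired(1:6, 1:5), "equal length")

  # n = 8 distinct differences: exact enumeration, cross-checked against the
  # base-R exact signed-rank p-value
  set.seed(11)
  a <- c(1.2, 5.4, 3.1, 7.9, 2.2, 9.5, 4.3, 8.8)
  b <- c(0.9, 1.2, 0.4, 2.2, 0.1, 3.3, 1.8, 2.0)
  r <- wilcoxon_paired(a, b)
  expect_true(r$exact)
  expect_equal(r$p_value, wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  expect_equal(r$p_value, oracle_signed_rank_p(a, b))
})

test_that("paired Wilcoxon is exact under ties and approximates well at larger n", {
  # tied absolute differences: enumeration with mid-ranks
  a <- c(3, 3, 5, 6, 2, 4, 4)
  b <- c(1, 1, 2, 2, 1, 2, 6)
  r <- wilcoxon_paired(a, b)
  expect_true(r$exact)
  expect_equal(r$p_value, oracle_signed_rank_p(a, b))

  # n > 12 falls back to the tie-corrected normal approximation; base R uses
  # the same classical formula once ties force it off the exact path
  set.seed(4)
  x <- sample(1:6, 30, replace = TRUE)
  y <- pmax(0, x - sample(0:3, 30, replace = TRUE))
  keep <- x != y
  r2 <- wilcoxon_paired(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, correct = TRUE))
  expect_false(r2$exact)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney matches enumeration and is symmetric", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 arrangements as extreme
  expect_equal(r$p_value, oracle_mann_whitney_p(c(1, 2, 3), c(4, 5, 6)))

  set.seed(8)
  a <- sample(1:9, 6, replace = TRUE)
  b <- sample(2:10, 7, replace = TRUE)
  ra <- mann_whitney(a, b); rb <- mann_whitney(b, a)
  expect_equal(ra$statistic + rb$statistic, length(a) * length(b))
  expect_equal(ra$p_value, rb$p_value)

  ident <- mann_whitney(c(2, 2, 4), c(2, 2, 4))
  expect_gt(ident$p_value, 0.99)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")

  # large-sample route against base R's tie-corrected normal approximation
  set.seed(9)
  x <- sample(1:8, 25, replace = TRUE)
  y <- sample(2:9, 30, replace = TRUE)
  r2 <- mann_whitney(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_false(r2$exact)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("chi-square matches base R with auto Yates and validates marginals", {
  tab23 <- rbind(c(591, 379, 170), c(631, 347, 132))
  r <- chi_square(tab23)
  ref <- chisq.test(tab23, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  expect_equal(r$df, 2)

  tab22 <- rbind(c(508, 632), c(312, 798))
  r2 <- chi_square(tab22)
  ref2 <- chisq.test(tab22, correct = TRUE)
  expect_true(r2$yates)
  expect_equal(r2$statistic, unname(ref2$statistic))
  expect_equal(r2$p_value, ref2$p.value)

  same <- rbind(c(10, 20), c(10, 20))
  expect_equal(chi_square(same)$statistic, 0)
  expect_equal(chi_square(same)$p_value, 1)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Yates-corrected statistic never exceeds the uncorrected one", {
  set.seed(21)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, lambda = sample(3:40, 1)) + 1, 2, 2)
    expect_lte(chi_square(tab, yates = "on")$statistic,
               chi_square(tab, yates = "off")$statistic)
  }
})

test_that("marginal-homogeneity alternative reduces to McNemar for 2 levels", {
  set.seed(5)
  x <- sample(c("a", "b"), 40, replace = TRUE)
  y <- sample(c("a", "b"), 40, replace = TRUE)
  r <- marginal_homogeneity(x, y)
  ref <- mcnemar.test(table(factor(x), factor(y)), correct = TRUE)
  expect_equal(r$p_value, ref$p.value)
})

test_that("tidy() methods return one-row tibbles for test objects", {
  r <- mann_whitney(1:5, 3:9)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("statistic", "p.value", "exact") %in% names(td)))
})
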