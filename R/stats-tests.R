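#' Median and interquartile range
#'
#' Summary convention used throughout the site-level tables: median with
#' 25th/75th percentiles by linear interpolation (R quantile type 7). The
#' convention is recorded in the result so printed IQRs are auditable.
#'
#' @param values numeric vector, at least one value.
#' @return Named numeric vector `c(median, q1, q3)` with attribute
#'   `convention`.
#' @examples
#' median_iqr(c(1, 2, 3, 4)) # 2.5, 1.75, 3.25
#' @export
median_iqr <- function(values) {
  if (!length(values)) abort("`values` must contain at least one value.")
  q <- quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  structure(c(median = q[1], q1 = q[2], q3 = q[3]),
            convention = "linear interpolation (quantile type 7)")
}

format_median_iqr <- function(values, unit = "") {
  m <- median_iqr(values)
  num <- function(x) formatC(x, format = "fg", digits = 3)
  if (m["q1"] == m["q3"]) {
    sprintf("%s [%s]%s", num(m["median"]), num(m["q1"]), unit)
  } else {
    sprintf("%s [%s, %s]%s", num(m["median"]), num(m["q1"]), num(m["q3"]), unit)
  }
}

new_perio_test <- function(method, statistic, p_value, n, exact,
                           degenerate = FALSE, ...) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value, n = n,
         exact = exact, degenerate = degenerate, ...),
    class = "perio_test"
  )
}

#' @export
print.perio_test <- function(x, ...) {
  cat(sprintf("<perio_test> %s\n  statistic = %.6g, p = %.4g, n = %s (%s%s)\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = "x"),
              if (x$exact) "exact" else "normal approximation",
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @export
tidy.perio_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p.value = x$p_value,
         n = paste(x$n, collapse = "x"), exact = x$exact,
         degenerate = x$degenerate)
}

two_sided_from_dist <- function(support, prob, observed) {
  lo <- sum(prob[support <= observed + 1e-9])
  hi <- sum(prob[support >= observed - 1e-9])
  min(1, 2 * min(lo, hi))
}

#' Paired Wilcoxon signed-rank test
#'
#' Classical treatment: zero differences are dropped, tied absolute
#' differences receive mid-ranks, and the two-tailed p-value comes from
#' exhaustive enumeration of all sign assignments when at most 12 non-zero
#' pairs remain (exact even under ties), otherwise from the normal
#' approximation with tie-corrected variance and continuity correction.
#' When every difference is zero the test is degenerate and p = 1.
#'
#' @param x_t0,x_t1 paired numeric vectors (at least 5 pairs).
#' @return A `perio_test` with the signed-rank statistic `V` (sum of ranks
#'   of positive differences) and the two-tailed p-value.
#' @export
wilcoxon_paired <- function(x_t0, x_t1) {
  if (length(x_t0) != length(x_t1)) abort("paired vectors must have equal length.")
  if (length(x_t0) < 5L) abort("at least 5 pairs are required.")
  d <- x_t0 - x_t1
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(new_perio_test("Wilcoxon signed-rank (paired)", statistic = 0,
                          p_value = 1, n = length(x_t0), exact = TRUE,
                          degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 12L) {
    # enumerate the 2^n sign assignments via a generating-function
    # convolution over doubled ranks (mid-ranks are half-integers)
    r2 <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(r2)))
    for (rr in r2) {
      shifted <- c(rep(0, rr), counts[seq_len(length(counts) - rr)])
      counts <- counts + shifted
    }
    support <- (seq_along(counts) - 1) / 2
    p <- two_sided_from_dist(support, counts / 2^n, v)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    if (v == mu) z <- 0
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  new_perio_test("Wilcoxon signed-rank (paired)", statistic = v, p_value = p,
                 n = n, exact = exact)
}

#' Mann-Whitney U test
#'
#' Two-tailed rank-sum test for independent groups: exact by exhaustive
#' enumeration of all group assignments when both groups have at most 8
#' observations (exact even under ties), otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return A `perio_test` with the U statistic for group `a` and the
#'   two-tailed p-value.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) abort("both groups must be non-empty.")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na <= 8L && nb <= 8L) {
    combos <- utils::combn(n, na)
    usup <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p <- two_sided_from_dist(sort(unique(usup)),
                             tabulate(match(usup, sort(unique(usup)))) / ncol(combos),
                             u)
    exact <- TRUE
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    if (u == mu) z <- 0
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  new_perio_test("Mann-Whitney U", statistic = u, p_value = min(p, 1),
                 n = c(na, nb), exact = exact)
}

#' Pearson chi-square test for contingency tables
#'
#' Pearson statistic with the Yates continuity correction applied, in
#' `"auto"` mode, exactly when the table is 2x2 — the convention for
#' comparing category counts between visits (no correction on the 2x3
#' category table, Yates on 2x2 tables such as bleeding on probing).
#'
#' @param table a matrix of counts.
#' @param yates `"auto"` (2x2 only), `"on"` or `"off"`.
#' @return A `perio_test` with `statistic` (chi-square), `df` and the
#'   upper-tail p-value.
#' @examples
#' chi_square(rbind(c(591, 379, 170), c(631, 347, 132)))$p_value # 0.0287
#' @export
chi_square <- function(table, yates = c("auto", "on", "off")) {
  yates <- match.arg(yates)
  tab <- as.matrix(table)
  if (any(tab < 0)) abort("counts must be non-negative.")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) abort("zero marginal in contingency table.")
  expected <- outer(rs, cs) / sum(tab)
  correct <- switch(yates, auto = all(dim(tab) == c(2L, 2L)), on = TRUE, off = FALSE)
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- pchisq(stat, df, lower.tail = FALSE)
  new_perio_test(
    if (correct) "Pearson chi-square (Yates)" else "Pearson chi-square",
    statistic = stat, p_value = p, n = sum(tab), exact = FALSE,
    df = df, expected = expected, yates = correct
  )
}

#' Marginal-homogeneity alternative for paired categories
#'
#' The category-count comparison between visits treats the two visits as
#' independent samples (unpaired chi-square), the convention replicated from
#' clinical reporting; since the same sites are probed twice, a
#' marginal-homogeneity (McNemar for 2 categories) test is the paired
#' alternative. Offered as an optional extra; nothing calls it by default.
#'
#' @param x_t0,x_t1 paired categorical vectors (same length).
#' @return A `perio_test` (Stuart-Maxwell marginal homogeneity; reduces to
#'   McNemar with continuity correction for 2 categories).
#' @export
marginal_homogeneity <- function(x_t0, x_t1) {
  if (length(x_t0) != length(x_t1)) abort("paired vectors must have equal length.")
  lev <- sort(unique(c(as.character(x_t0), as.character(x_t1))))
  tab <- table(factor(x_t0, lev), factor(x_t1, lev))
  if (length(lev) == 2L) {
    ht <- stats::mcnemar.test(tab, correct = TRUE)
    return(new_perio_test("McNemar (continuity corrected)",
                          statistic = unname(ht$statistic),
                          p_value = ht$p.value, n = length(x_t0), exact = FALSE,
                          df = unname(ht$parameter)))
  }
  k <- length(lev)
  d <- (rowSums(tab) - colSums(tab))[-k]
  s <- matrix(0, k - 1, k - 1)
  for (i in seq_len(k - 1)) {
    for (j in seq_len(k - 1)) {
      s[i, j] <- if (i == j) {
        rowSums(tab)[i] + colSums(tab)[i] - 2 * tab[i, i]
      } else {
        -(tab[i, j] + tab[j, i])
      }
    }
  }
  stat <- as.numeric(t(d) %*% solve(s) %*% d)
  df <- k - 1
  new_perio_test("Stuart-Maxwell marginal homogeneity", statistic = stat,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 n = length(x_t0), exact = FALSE, df = df)
}
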