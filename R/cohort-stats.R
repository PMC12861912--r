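test_result <- function(method, statistic, df = NA_real_, p) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p = unname(p)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g\n", x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(" (df = %.2f)", x$df), x$p))
  invisible(x)
}

#' Welch two-sample t test from group summaries
#'
#' Unequal-variance (Welch) t test computed directly from per-group means,
#' standard deviations and sizes, with the Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. This is the form used to reproduce
#' published group comparisons from summary tables.
#'
#' @param mean1,sd1,n1 First group summary (sd > 0, n >= 2).
#' @param mean2,sd2,n2 Second group summary.
#' @return A `test_result` with fields `statistic` (t), `df`, `p`.
#' @examples
#' welch_t(62.47, 8.85, 30, 61.51, 8.01, 67)$statistic
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort_invalid("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) abort_invalid("standard deviations must be positive")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  test_result("Welch t", t, df, 2 * stats::pt(-abs(t), df))
}

#' Welch two-sample t test from raw samples
#'
#' Computes group moments and delegates to [welch_t()].
#'
#' @param x,y Numeric samples (each length >= 2, non-degenerate).
#' @return A `test_result`.
#' @export
welch_t_samples <- function(x, y) {
  welch_t(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Mann-Whitney U test (tie-corrected normal approximation)
#'
#' U statistic via midranks; z from the normal approximation with tie
#' correction and no continuity correction; two-sided p-value.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return A `test_result` with `statistic` = z and an extra field `U`
#'   (the U statistic for `x`, i.e. the number of (x, y) pairs with
#'   x > y, counting ties 1/2).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort_invalid("samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (v > 0) (U - mu) / sqrt(v) else 0
  out <- test_result("Mann-Whitney U", z, p = 2 * stats::pnorm(-abs(z)))
  out$U <- U
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' Chi-square without continuity correction, df = 1. Counts are given as
#' `(a, b, c, d)` = (group1 positive, group1 negative, group2 positive,
#' group2 negative) or as a 2x2 matrix.
#'
#' @param a,b,c,d Non-negative integer cell counts, or `a` a 2x2 matrix.
#' @return A `test_result`.
#' @examples
#' pearson_chi2(21, 9, 21, 46)$statistic  # smoking: 12.613
#' @export
pearson_chi2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(m < 0) || sum(m) < 1) abort_invalid("counts must be non-negative, total >= 1")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    abort("a zero marginal makes the chi-square test degenerate",
          class = "rsilung_degenerate_table")
  ct <- stats::chisq.test(m, correct = FALSE)
  test_result("Pearson chi-square", ct$statistic, ct$parameter, ct$p.value)
}

#' Odds ratio and Wald confidence interval for a 2x2 table
#'
#' `OR = (a d) / (b c)` with the Wald interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity
#' correction is applied; a zero cell is an error.
#'
#' @inheritParams pearson_chi2
#' @param conf Confidence level (default 0.95).
#' @return A list with `or`, `ci` (low, high), `z`, `p`.
#' @examples
#' odds_ratio_2x2(21, 9, 21, 46)$or  # 5.111
#' @export
odds_ratio_2x2 <- function(a, b = NULL, c = NULL, d = NULL, conf = 0.95) {
  m <- if (is.matrix(a)) a else matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(m <= 0))
    abort("all four cells must be positive for a Wald odds ratio",
          class = "rsilung_zero_cell")
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  se <- sqrt(sum(1 / m))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  z <- log(or) / se
  list(or = or, ci = exp(log(or) + c(-zq, zq) * se),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Intraclass correlation coefficient, two-way random, absolute agreement
#'
#' Single-measure ICC(A,1) from the two-way ANOVA decomposition of a
#' subjects x raters layout with two raters. Absolute agreement penalizes
#' systematic offsets between readers, unlike the consistency ICC.
#'
#' @param reader1,reader2 Paired measurements, equal length >= 3.
#' @return The ICC value (in (-1, 1]).
#' @export
icc_agreement <- function(reader1, reader2) {
  n <- length(reader1)
  if (length(reader2) != n || n < 3)
    abort_invalid("need paired readings of equal length >= 3")
  x <- cbind(reader1, reader2); k <- 2
  grand <- mean(x)
  if (sum((x - grand)^2) == 0)
    abort("total variance is zero; ICC undefined", class = "rsilung_undefined_icc")
  subj <- rowMeans(x); rater <- colMeans(x)
  msr <- k * sum((subj - grand)^2) / (n - 1)
  msc <- n * sum((rater - grand)^2) / (k - 1)
  sse <- sum((x - outer(subj, rep(1, k)) - outer(rep(1, n), rater) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Choose and run the appropriate two-group test for a continuous variable
#'
#' Shapiro-Wilk normality is assessed per group at alpha = 0.05; if both
#' groups look normal, the Welch t test (sample form) is used, otherwise
#' the Mann-Whitney U test. The branch taken is recorded in the result.
#'
#' @param x,y Continuous samples.
#' @param alpha Normality-gate significance level.
#' @return A `test_result` with an extra field `branch`
#'   (`"welch_t"` or `"mann_whitney"`).
#' @export
select_test <- function(x, y, alpha = 0.05) {
  normal <- function(v) stats::shapiro.test(v)$p.value > alpha
  if (normal(x) && normal(y)) {
    out <- welch_t_samples(x, y)
    out$branch <- "welch_t"
  } else {
    out <- mann_whitney(x, y)
    out$branch <- "mann_whitney"
  }
  out
}

fmt_mean_sd <- function(v, digits = 3) {
  sprintf("%.*f ± %.*f", digits, mean(v), digits, stats::sd(v))
}

fmt_median_iqr <- function(v, digits = 3) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.*f (%.*f, %.*f)", digits, q[2], digits, q[1], digits, q[3])
}

#' Group-comparison (descriptive) table for a cohort
#'
#' For each continuous variable the normality-gated test from
#' [select_test()] decides both the test and the summary style (mean +/-
#' SD for the t branch, median (IQR) for the rank branch); sex and smoking
#' are compared with the uncorrected chi-square test. Fractions are
#' displayed x 10^-2 and ADC x 10^-3 mm^2/s; computation stays in base
#' units.
#'
#' @param cohort Cohort data frame, see [generate_cohort()].
#' @return A data frame with columns `variable`, `scc`, `ac`, `test`,
#'   `statistic`, `p`.
#' @export
descriptive_table <- function(cohort) {
  scc <- cohort[cohort$subtype == "SCC", ]
  ac <- cohort[cohort$subtype == "AC", ]
  display_scale <- c(age = 1, diameter = 1, suvmax = 1,
                     f1 = 100, f2 = 100, f3 = 100, adc = 1000)
  rows <- list()
  for (v in names(display_scale)) {
    x <- scc[[v]] * display_scale[[v]]
    y <- ac[[v]] * display_scale[[v]]
    res <- select_test(scc[[v]], ac[[v]])
    fmt <- if (res$branch == "welch_t") fmt_mean_sd else fmt_median_iqr
    rows[[v]] <- data.frame(
      variable = v, scc = fmt(x), ac = fmt(y),
      test = res$method, statistic = res$statistic, p = res$p,
      stringsAsFactors = FALSE)
  }
  for (v in c("sex", "smoking")) {
    pos <- if (v == "sex") {
      list(s = sum(scc$sex == "male"), a = sum(ac$sex == "male"), lab = "male")
    } else {
      list(s = sum(scc$smoking == 1), a = sum(ac$smoking == 1), lab = "smoker")
    }
    res <- pearson_chi2(pos$s, nrow(scc) - pos$s, pos$a, nrow(ac) - pos$a)
    rows[[v]] <- data.frame(
      variable = v,
      scc = sprintf("%d/%d (%.2f%%)", pos$s, nrow(scc), 100 * pos$s / nrow(scc)),
      ac = sprintf("%d/%d (%.2f%%)", pos$a, nrow(ac), 100 * pos$a / nrow(ac)),
      test = res$method, statistic = res$statistic, p = res$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
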