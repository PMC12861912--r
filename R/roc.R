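# DeLong placement values via midranks. For positive scores X (m of them)
# and negative scores Y (n), V10[i] is the proportion of negatives each
# positive outranks (ties 1/2) and V01[j] the mirror quantity; AUC is the
# mean of either set.
delong_placements <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Empirical ROC analysis with DeLong interval and Youden cutoff
#'
#' The AUC is the concordance probability (ties counted 1/2), its
#' confidence interval uses the DeLong structural-component variance, and
#' the reported cutoff maximizes the Youden index J = sensitivity +
#' specificity - 1 over thresholds placed midway between adjacent observed
#' scores; J ties are broken toward the higher-sensitivity cutoff.
#'
#' @param scores Numeric scores (risk of the positive class).
#' @param labels Binary class labels (factor/character with `positive`,
#'   logical, or 0/1).
#' @param positive Positive class label for factor/character input.
#' @param direction `">"` if higher scores indicate the positive class,
#'   `"<"` for the reverse, or `"auto"` (default) to choose the direction
#'   giving AUC >= 0.5.
#' @param conf Confidence level for the AUC interval.
#' @return An object of class `roc_result`: `auc`, `var`, `ci` (clipped
#'   to \[0, 1\]), `cutoff`, `sensitivity`, `specificity`, `direction`,
#'   and `operating_points` (threshold, sensitivity, specificity, youden).
#'   With direction `"<"`, cases at or below `cutoff` are called positive.
#' @examples
#' sc <- rep(c(1, 0, 1, 0), c(21, 9, 21, 46))
#' y <- rep(c("SCC", "SCC", "AC", "AC"), c(21, 9, 21, 46))
#' roc_analysis(sc, y, positive = "SCC")$auc  # 0.693
#' @export
roc_analysis <- function(scores, labels, positive = NULL,
                         direction = c("auto", ">", "<"), conf = 0.95) {
  direction <- match.arg(direction)
  pos <- binary_outcome(labels, positive) == 1
  if (length(scores) != length(pos)) abort_invalid("scores and labels lengths differ")
  if (anyNA(scores)) abort_invalid("scores must not contain NA")

  s <- scores
  if (direction == "auto") {
    direction <- if (delong_placements(s, pos)$auc >= 0.5) ">" else "<"
  }
  if (direction == "<") s <- -s
  pl <- delong_placements(s, pos)
  auc <- pl$auc
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(auc + c(-zq, zq) * sqrt(v), 0), 1)

  su <- sort(unique(s))
  thr <- c(-Inf, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!pos] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]          # ties -> higher sensitivity
  cutoff <- thr[best]
  if (direction == "<") {
    cutoff <- -cutoff
    ops <- data.frame(threshold = rev(-thr), sensitivity = rev(sens),
                      specificity = rev(spec), youden = rev(j))
  } else {
    ops <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec, youden = j)
  }
  structure(list(auc = auc, var = v, ci = ci, cutoff = cutoff,
                 sensitivity = sens[best], specificity = spec[best],
                 direction = direction, operating_points = ops),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f-%.3f), cutoff %.4g (direction %s), sens %.2f%%, spec %.2f%%\n",
              x$auc, x$ci[1], x$ci[2], x$cutoff, x$direction,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same cases using
#' the paired structural-components variance. Scores are taken as
#' oriented (higher score = positive class); orient beforehand if needed.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary class labels.
#' @param positive Positive class label for factor/character input.
#' @return List with `auc_a`, `auc_b`, `delta` (a - b), `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b))
    abort_invalid("score vectors must be paired (equal length)")
  pos <- binary_outcome(labels, positive) == 1
  pa <- delong_placements(scores_a, pos)
  pb <- delong_placements(scores_b, pos)
  delta <- pa$auc - pb$auc
  v <- stats::var(pa$v10 - pb$v10) / pa$m + stats::var(pa$v01 - pb$v01) / pa$n
  z <- if (v > 0) delta / sqrt(v) else if (delta == 0) 0 else sign(delta) * Inf
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
       p = if (v > 0 || delta == 0) 2 * stats::pnorm(-abs(z)) else 0)
}

auc_of <- function(scores, pos) delong_placements(scores, pos)$auc

#' Bootstrap internal validation of a logistic model
#'
#' Optimism-corrected AUC by the bootstrap: for each of `B` resamples
#' (drawn with replacement, stratified by outcome so both classes are
#' always present) the model is refitted; its AUC on the resample and on
#' the original cohort are recorded, and the mean difference is the
#' optimism subtracted from the apparent AUC. The bootstrap mean AUC and
#' the 2.5/97.5 percentile interval of the resample AUCs are also
#' reported, since published single-number bootstrap summaries are often
#' ambiguous between the two.
#'
#' Within a resample the refit is used even when it separates the
#' resampled classes: the divergent coefficients still order the cases,
#' so the resample and original-data AUCs remain well defined (the usual
#' convention in optimism-bootstrap implementations). Only refits that
#' fail outright count as failures, and at least 95% of the `B`
#' replicates must succeed.
#'
#' @param cohort Cohort data frame.
#' @param candidates Predictors of the model being validated.
#' @param B Number of bootstrap resamples (>= 1; 1000 typical).
#' @param seed Optional integer seed.
#' @param outcome,positive Outcome column and positive class.
#' @return List: `apparent_auc`, `boot_mean_auc`, `boot_ci`,
#'   `optimism`, `corrected_auc`, `B`, `n_failed`, `seed`.
#' @export
bootstrap_validate <- function(cohort, candidates, B = 1000, seed = NULL,
                               outcome = "subtype", positive = "SCC") {
  if (B < 1) abort_invalid("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  full <- multivariate_fit(cohort, candidates, elimination = "none",
                           outcome = outcome, positive = positive)
  pos <- binary_outcome(cohort[[outcome]], positive) == 1
  apparent <- auc_of(full$fitted, pos)
  idx_pos <- which(pos); idx_neg <- which(!pos)
  xf_orig <- predictor_frame(cohort, candidates)
  dat <- cbind(xf_orig, .y = as.integer(pos))

  boot_auc <- orig_auc <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
    res <- tryCatch({
      fit_b <- suppressWarnings(
        stats::glm(.y ~ ., data = dat[idx, ], family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
      pr_orig <- stats::predict(fit_b, newdata = xf_orig, type = "response")
      c(auc_of(unname(stats::fitted(fit_b)), pos[idx]), auc_of(pr_orig, pos))
    }, error = function(e) NULL)
    if (!is.null(res)) { boot_auc[b] <- res[1]; orig_auc[b] <- res[2] }
  }
  ok <- !is.na(boot_auc)
  if (sum(ok) < 0.95 * B)
    abort(sprintf("only %d/%d bootstrap refits succeeded", sum(ok), B),
          class = "rsilung_bootstrap_failure")
  optimism <- mean(boot_auc[ok] - orig_auc[ok])
  list(apparent_auc = apparent,
       boot_mean_auc = mean(boot_auc[ok]),
       boot_ci = unname(stats::quantile(boot_auc[ok], c(0.025, 0.975))),
       optimism = optimism,
       corrected_auc = apparent - optimism,
       B = B, n_failed = B - sum(ok), seed = seed)
}

#' Calibration curve and logistic recalibration
#'
#' Groups predictions into equal-count bins (deciles by default) and
#' compares mean predicted probability with observed event frequency per
#' bin; also fits the logistic recalibration of outcomes on
#' logit(prediction), whose slope/intercept are 1/0 for a perfectly
#' calibrated model.
#'
#' @param predicted Predicted probabilities in (0, 1).
#' @param outcomes Binary outcomes.
#' @param bins Number of equal-count bins (reduced with a warning if there
#'   are fewer cases than bins).
#' @return List with `points` (data frame: bin, n, mean_predicted,
#'   observed) and `slope`, `intercept` of the recalibration fit (NA if
#'   predictions are constant).
#' @export
calibration_curve <- function(predicted, outcomes, bins = 10) {
  y <- binary_outcome(outcomes)
  if (any(predicted <= 0 | predicted >= 1))
    abort_invalid("predictions must lie strictly in (0, 1)")
  n <- length(predicted)
  if (n < bins) {
    warning(sprintf("only %d cases; reducing bins from %d to %d", n, bins, n))
    bins <- n
  }
  ord <- order(predicted)
  grp_of_sorted <- ceiling(seq_len(n) / n * bins)
  # collapse bins that carry identical predictions (e.g. constant scores)
  key <- tapply(predicted[ord], grp_of_sorted, mean)
  grp_id <- match(key, unique(key))[grp_of_sorted]
  grp <- integer(n); grp[ord] <- grp_id
  pts <- data.frame(
    bin = sort(unique(grp)),
    n = as.integer(table(grp)),
    mean_predicted = as.numeric(tapply(predicted, grp, mean)),
    observed = as.numeric(tapply(y, grp, mean)))

  lp <- stats::qlogis(predicted)
  if (stats::sd(lp) == 0) {
    slope <- NA_real_; intercept <- NA_real_
  } else {
    rc <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial()))
    slope <- unname(stats::coef(rc)[2]); intercept <- unname(stats::coef(rc)[1])
  }
  list(points = pts, slope = slope, intercept = intercept)
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at each threshold probability pt,
#' `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)` (cases with predicted
#' probability >= pt are treated), with companion treat-all and
#' treat-none strategies.
#'
#' @param predicted Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param thresholds Threshold grid, strictly inside (0, 1).
#' @return Data frame: `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(predicted, outcomes,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- binary_outcome(outcomes)
  if (any(thresholds <= 0 | thresholds >= 1))
    abort_invalid("thresholds must lie strictly in (0, 1)")
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    treat <- predicted >= pt
    tp <- sum(treat & y == 1) / n
    fp <- sum(treat & y == 0) / n
    tp - fp * pt / (1 - pt)
  }, numeric(1))
  data.frame(threshold = thresholds,
             net_benefit = nb,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}
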