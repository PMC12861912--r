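# Binary outcome coercion: factor (last level positive unless `positive`
# given), logical, or 0/1 numeric.
binary_outcome <- function(y, positive = NULL) {
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(y)
    if (is.null(positive)) positive <- levels(y)[nlevels(y)]
    out <- as.integer(y == positive)
  } else {
    out <- as.integer(as.numeric(y) != 0)
  }
  if (length(unique(out)) < 2)
    abort_invalid("outcome must contain both classes")
  out
}

# Predictor frame in report units: sex becomes a male indicator ("male"
# is accepted as an alias so screened names round-trip), volume fractions
# are scaled x100 and ADC x1000 so odds ratios are per printed table
# unit. Everything else passes through numerically.
predictor_frame <- function(cohort, candidates) {
  cols <- ifelse(candidates == "male", "sex", candidates)
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    abort_invalid(paste("candidates not in cohort:", paste(missing, collapse = ", ")))
  scale <- c(f1 = 100, f2 = 100, f3 = 100, adc = 1000)
  out <- lapply(cols, function(v) {
    col <- cohort[[v]]
    if (v == "sex") as.integer(col == "male")
    else if (v %in% names(scale)) as.numeric(col) * scale[[v]]
    else as.numeric(col)
  })
  names(out) <- ifelse(cols == "sex", "male", cols)
  as.data.frame(out)
}

single_separator <- function(x, y1) {
  # does this predictor alone separate the classes perfectly?
  a <- x[y1 == 1]; b <- x[y1 == 0]
  min(a) > max(b) || max(a) < min(b)
}

#' Fit a logistic regression model by maximum likelihood
#'
#' Iteratively reweighted least squares (tolerance 1e-8, at most 100
#' iterations) with an intercept always included; Wald standard errors
#' from the observed information. Perfect separation and collinear
#' predictors raise classed errors naming the offending predictor rather
#' than returning divergent estimates.
#'
#' @param x Data frame or matrix of predictors.
#' @param y Binary outcome: factor/character (see `positive`), logical, or
#'   0/1 numeric.
#' @param positive For factor outcomes, the level modelled as 1.
#' @return An object of class `rsilung_logit`: `coefficients`, `se`,
#'   `or`, `ci` (Wald 95\%), `p`, `converged`, `iterations`,
#'   `fitted` (probabilities of the positive class), and the underlying
#'   `glm` object for prediction.
#' @examples
#' d <- data.frame(smoking = rep(c(1, 0, 1, 0), c(21, 9, 21, 46)))
#' y <- rep(c("SCC", "AC"), c(30, 67))
#' exp(coef(logistic_fit(d, y, positive = "SCC")$glm))[2]  # OR 5.111
#' @export
logistic_fit <- function(x, y, positive = NULL) {
  x <- as.data.frame(x)
  y1 <- binary_outcome(y, positive)
  if (nrow(x) != length(y1)) abort_invalid("x and y lengths differ")
  dat <- cbind(x, .y = y1)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    abort(paste("collinear predictors dropped by the fit:",
                paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "rsilung_collinearity")
  if (fit$deviance < 1e-6) {
    sep <- names(x)[vapply(x, function(col)
      is.numeric(col) && single_separator(as.numeric(col), y1), logical(1))]
    who <- if (length(sep)) paste(sep, collapse = ", ")
           else "a linear combination of predictors"
    abort(paste("perfect separation by", who), class = "rsilung_separation")
  }
  if (!fit$converged)
    abort(sprintf("IRLS did not converge in %d iterations", fit$iter),
          class = "rsilung_nonconvergence")
  se <- sqrt(diag(stats::vcov(fit)))
  z <- cf / se
  structure(list(
    predictors = names(x),
    coefficients = cf, se = se,
    or = exp(cf), ci = exp(cbind(low = cf - 1.96 * se, high = cf + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(z)),
    converged = fit$converged, iterations = fit$iter,
    fitted = unname(stats::fitted(fit)), glm = fit),
    class = "rsilung_logit")
}

#' @export
print.rsilung_logit <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients, se = x$se, or = x$or,
                    or_low = x$ci[, "low"], or_high = x$ci[, "high"], p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Univariate logistic screen of candidate predictors
#'
#' One single-predictor logistic fit per candidate; predictors passing at
#' `alpha` form the entry set for the multivariate model. Separation or
#' other fit failures for one candidate are recorded without aborting the
#' screen.
#'
#' @param cohort Cohort data frame.
#' @param candidates Predictor names (column names; `"sex"` is coded as a
#'   male indicator).
#' @param alpha Significance threshold for passing (default 0.05).
#' @param outcome,positive Outcome column and positive class.
#' @return Data frame with `predictor`, `or`, `ci_low`, `ci_high`, `p`,
#'   `pass`, `note`.
#' @export
univariate_screen <- function(cohort, candidates, alpha = 0.05,
                              outcome = "subtype", positive = "SCC") {
  if (!length(candidates))
    return(data.frame(predictor = character(), or = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p = numeric(), pass = logical(), note = character()))
  xf <- predictor_frame(cohort, candidates)
  y <- cohort[[outcome]]
  rows <- lapply(names(xf), function(v) {
    res <- tryCatch(logistic_fit(xf[v], y, positive = positive),
                    rsilung_error = function(e) e)
    if (inherits(res, "rsilung_error"))
      return(data.frame(predictor = v, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, pass = FALSE,
                        note = conditionMessage(res), stringsAsFactors = FALSE))
    data.frame(predictor = v, or = unname(res$or[2]),
               ci_low = res$ci[2, "low"], ci_high = res$ci[2, "high"],
               p = unname(res$p[2]), pass = unname(res$p[2]) < alpha,
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multivariate logistic model with optional backward elimination
#'
#' Joint logistic fit on the candidates that passed the univariate screen.
#' With `elimination = "backward"`, the predictor with the largest Wald
#' p-value above 0.05 is dropped and the model refitted until every
#' remaining predictor has p <= 0.05. The fitted probabilities of the
#' positive class are the combined diagnostic score.
#'
#' @param cohort Cohort data frame.
#' @param candidates Predictor names entering the model.
#' @param elimination `"none"` (default) or `"backward"`.
#' @param outcome,positive Outcome column and positive class.
#' @return An `rsilung_logit` with an extra field `retained` (predictor
#'   names in the final model, in entry order).
#' @export
multivariate_fit <- function(cohort, candidates,
                             elimination = c("none", "backward"),
                             outcome = "subtype", positive = "SCC") {
  elimination <- match.arg(elimination)
  if (!length(candidates)) abort_invalid("need at least one candidate predictor")
  xf <- predictor_frame(cohort, candidates)
  y <- cohort[[outcome]]
  keep <- names(xf)
  repeat {
    fit <- logistic_fit(xf[keep], y, positive = positive)
    if (elimination == "none") break
    p <- fit$p[-1]  # drop intercept
    worst <- which.max(p)
    if (length(keep) <= 1 || p[worst] <= 0.05) break
    keep <- setdiff(keep, names(p)[worst])
  }
  fit$retained <- keep
  fit
}
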