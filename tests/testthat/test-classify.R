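test_that("a saturated binary predictor reproduces the closed-form odds ratio", {
  v <- smoking_cohort_vectors()
  fit <- logistic_fit(data.frame(smoking = v$scores), v$labels, positive = "SCC")
  closed <- odds_ratio_2x2(21, 9, 21, 46)
  expect_equal(unname(fit$or[2]), closed$or, tolerance = 1e-6)
  expect_equal(unname(fit$ci[2, "low"]), closed$ci[1], tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("an uninformative balanced predictor gets a zero coefficient", {
  x <- rep(c(0, 1, 0, 1), each = 25)
  y <- rep(c(0, 0, 1, 1), each = 25)
  fit <- logistic_fit(data.frame(x = x), y)
  expect_equal(unname(fit$coefficients[2]), 0, tolerance = 1e-8)
})

test_that("coefficients agree with a direct likelihood maximization", {
  d <- data.frame(x = c(0.2, 1.1, 2.3, 3.0, 4.2, 5.1))
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- logistic_fit(d, y)
  nll <- function(par) {
    eta <- par[1] + par[2] * d$x
    -sum(y * eta - log(1 + exp(eta)))
  }
  ref <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coefficients), ref$par, tolerance = 1e-4)
})

test_that("separation and collinearity are reported, not returned", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  err <- tryCatch(logistic_fit(data.frame(marker = x), y),
                  rsilung_separation = function(e) e)
  expect_s3_class(err, "rsilung_separation")
  expect_match(conditionMessage(err), "marker")

  set.seed(2)
  z <- rnorm(40)
  yy <- rbinom(40, 1, plogis(z))
  expect_error(logistic_fit(data.frame(a = z, b = 2 * z), yy),
               class = "rsilung_collinearity")
})

test_that("univariate screen handles published counts, noise, and edge cases", {
  v <- smoking_cohort_vectors()
  co <- data.frame(subtype = v$labels, smoking = v$scores)
  screen <- univariate_screen(co, "smoking")
  expect_true(screen$pass)
  expect_equal(screen$or, 5.111, tolerance = 1e-3)
  expect_lt(screen$p, 0.001)

  expect_equal(nrow(univariate_screen(co, character(0))), 0)

  # pure-noise candidate is excluded about 95% of the time at alpha 0.05
  set.seed(77)
  excluded <- replicate(500, {
    noise_co <- data.frame(subtype = rep(c("SCC", "AC"), c(30, 67)),
                           noise = rnorm(97))
    !univariate_screen(noise_co, "noise")$pass
  })
  expect_gt(mean(excluded), 0.92)
  expect_lt(mean(excluded), 0.98)
})

test_that("multivariate fit reduces to univariate for one candidate and
           backward elimination keeps the truly predictive set", {
  co <- generate_cohort(30, 67, seed = 4)
  uni <- univariate_screen(co, "f1")
  mv <- multivariate_fit(co, "f1")
  expect_equal(unname(mv$or[2]), uni$or, tolerance = 1e-10)

  set.seed(55)
  kept_right <- replicate(100, {
    n <- 2000
    d <- data.frame(f1 = rnorm(n), smoking = rbinom(n, 1, 0.5),
                    noise = rnorm(n))
    y <- rbinom(n, 1, plogis(-0.5 + 1.2 * d$f1 + 1.0 * d$smoking))
    d$subtype <- factor(ifelse(y == 1, "SCC", "AC"), levels = c("AC", "SCC"))
    mv <- multivariate_fit(d, c("f1", "smoking", "noise"),
                           elimination = "backward")
    setequal(mv$retained, c("f1", "smoking"))
  })
  expect_gte(mean(kept_right), 0.90)
})

test_that("ROC analysis reproduces published binary-predictor performance", {
  v <- smoking_cohort_vectors()
  r <- roc_analysis(v$scores, v$labels, positive = "SCC")
  expect_equal(r$auc, 0.693, tolerance = 5e-4)
  expect_equal(r$sensitivity, 0.7000, tolerance = 5e-5)
  expect_equal(r$specificity, 0.6866, tolerance = 5e-5)

  # binary score: AUC = (sens + spec) / 2 at the single operating point
  expect_equal(r$auc, (r$sensitivity + r$specificity) / 2, tolerance = 1e-12)

  male <- rep(c(1, 0, 1, 0), c(25, 5, 27, 40))
  lab <- rep(c("SCC", "SCC", "AC", "AC"), c(25, 5, 27, 40))
  expect_equal(roc_analysis(male, lab, positive = "SCC")$auc, 0.715,
               tolerance = 5e-4)
})

test_that("ROC boundary cases and cutoff conventions hold", {
  y <- rep(c(0, 1), each = 10)
  perfect <- c(rnorm(10, 0), rnorm(10, 0) + 100)
  expect_equal(roc_analysis(perfect, y)$auc, 1.0)
  expect_equal(roc_analysis(rep(1, 20), y)$auc, 0.5)
  expect_error(roc_analysis(rnorm(5), rep(1, 5)), class = "rsilung_invalid_argument")

  # cutoff is midway between adjacent scores and attains max Youden J
  sc <- c(1, 2, 3, 4, 5, 6)
  yy <- c(0, 0, 0, 1, 1, 1)
  r <- roc_analysis(sc, yy)
  expect_equal(r$cutoff, 3.5)
  expect_equal(max(r$operating_points$youden),
               r$sensitivity + r$specificity - 1)

  # auto direction flips a marker that is lower in the positive class
  co <- generate_cohort(30, 67, seed = 6)
  r2 <- roc_analysis(co$f1, co$subtype, positive = "SCC")
  expect_equal(r2$direction, "<")
  expect_gte(r2$auc, 0.5)
})

test_that("AUC, interval and DeLong variance agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(91)
  for (i in 1:5) {
    y <- rep(c(0, 1), c(40, 30))
    s <- rnorm(70) + y * runif(1, 0, 2)
    mine <- roc_analysis(s, y, direction = ">")
    ref <- pROC::roc(y, s, direction = "<", quiet = TRUE)
    expect_equal(mine$auc, as.numeric(ref$auc), tolerance = 1e-12)
    ci <- pROC::ci.auc(ref, method = "delong")
    expect_equal(mine$ci, as.numeric(ci)[c(1, 3)], tolerance = 1e-9)

    s2 <- s + rnorm(70, sd = 0.5)
    mine_dl <- delong_test(s, s2, y)
    ref_dl <- pROC::roc.test(ref, pROC::roc(y, s2, direction = "<", quiet = TRUE),
                             method = "delong", paired = TRUE)
    expect_equal(mine_dl$z, unname(ref_dl$statistic), tolerance = 1e-9)
    expect_equal(mine_dl$p, ref_dl$p.value, tolerance = 1e-9)
  }
})

test_that("DeLong test is null on identical or monotone-equivalent scores", {
  set.seed(3)
  y <- rep(c(0, 1), c(15, 10))
  s <- rnorm(25)
  r <- delong_test(s, s, y)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  r2 <- delong_test(s, exp(2 * s) + 5, y)
  expect_equal(r2$z, 0)
  expect_error(delong_test(s, s[-1], y), class = "rsilung_invalid_argument")
})

test_that("DeLong structural components match brute-force enumeration", {
  s <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9, 0.5, 0.6)
  pos <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  pl <- rsilung:::delong_placements(s, pos)
  ref <- oracle_placements(s, pos)
  expect_equal(pl$auc, ref$auc, tolerance = 1e-12)
  expect_equal(pl$v10, ref$v10, tolerance = 1e-12)
  expect_equal(pl$v01, ref$v01, tolerance = 1e-12)
})

test_that("AUC equals the scaled Mann-Whitney U on the same data", {
  set.seed(12)
  for (i in 1:10) {
    pos_scores <- sample(1:8, 14, replace = TRUE)
    neg_scores <- sample(1:8, 11, replace = TRUE)
    u <- mann_whitney(pos_scores, neg_scores)$U
    auc <- roc_analysis(c(pos_scores, neg_scores),
                        rep(c(1, 0), c(14, 11)), direction = ">")$auc
    expect_equal(auc, u / (14 * 11), tolerance = 1e-12)
  }
})

test_that("bootstrap validation is deterministic and corrects optimism", {
  co <- generate_cohort(30, 67, seed = 10)
  v1 <- bootstrap_validate(co, c("smoking", "f1", "adc", "suvmax"),
                           B = 100, seed = 1)
  v2 <- bootstrap_validate(co, c("smoking", "f1", "adc", "suvmax"),
                           B = 100, seed = 1)
  expect_identical(v1, v2)
  expect_lte(v1$boot_ci[1], v1$boot_mean_auc)
  expect_lte(v1$boot_mean_auc, v1$boot_ci[2])

  # optimism is positive in expectation: corrected <= apparent in most runs
  set.seed(23)
  shrunk <- replicate(20, {
    co <- generate_cohort(30, 67)
    v <- bootstrap_validate(co, c("smoking", "f1", "adc", "suvmax"), B = 60)
    v$corrected_auc <= v$apparent_auc
  })
  expect_gte(mean(shrunk), 0.9)
})

test_that("calibration recovers identity for self-generated outcomes", {
  set.seed(31)
  p <- runif(10000, 0.05, 0.95)
  y <- rbinom(10000, 1, p)
  cal <- calibration_curve(p, y)
  expect_equal(cal$slope, 1, tolerance = 0.05)
  expect_equal(cal$intercept, 0, tolerance = 0.05)
  expect_equal(nrow(cal$points), 10)
  expect_true(all(abs(cal$points$mean_predicted - cal$points$observed) < 0.1))

  # anti-calibrated predictions have negative recalibration slope
  anti <- calibration_curve(1 - p, y)
  expect_lt(anti$slope, 0)

  # constant predictions collapse to one usable bin
  yc <- rep(c(0, 1), 50)
  cc <- calibration_curve(rep(0.5, 100), yc)
  expect_equal(nrow(cc$points), 1)
  expect_equal(cc$points$observed, 0.5)

  expect_warning(calibration_curve(runif(6, 0.2, 0.8), rbinom(6, 1, 0.5)),
                 "reducing bins")
})

test_that("decision curve matches its closed forms", {
  set.seed(41)
  y <- rbinom(400, 1, 0.3)
  p <- plogis(rnorm(400) + y)
  dc <- decision_curve(p, y, thresholds = c(0.25, 0.5, 0.75))
  expect_true(all(dc$treat_none == 0))
  prev <- mean(y)
  expect_equal(dc$treat_all[dc$threshold == 0.5], 2 * prev - 1, tolerance = 1e-12)
  expect_true(all(dc$net_benefit <= prev + 1e-12))

  # perfect predictor: net benefit equals prevalence below all positive scores
  pp <- ifelse(y == 1, 0.95, 0.02)
  dcp <- decision_curve(pp, y, thresholds = c(0.1, 0.5, 0.9))
  expect_equal(dcp$net_benefit[1:2], rep(prev, 2), tolerance = 1e-12)

  expect_error(decision_curve(p, y, thresholds = c(0, 0.5)),
               class = "rsilung_invalid_argument")
})
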