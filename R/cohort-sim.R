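# Truncated-normal machinery. Generators for the volume fraction f1 and
# for ADC are truncated to their physical ranges; the underlying (mu,
# sigma) are solved numerically so the *truncated* distribution has the
# requested mean and sd (naive truncation would bias the group means the
# cohort is calibrated to).

tnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- if (is.finite(a)) stats::dnorm(a) else 0
  db <- if (is.finite(b)) stats::dnorm(b) else 0
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (ada - bdb) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

tnorm_match <- function(mean, sd, lo, hi) {
  obj <- function(par) {
    mm <- tnorm_moments(par[1], exp(par[2]), lo, hi)
    (mm$mean - mean)^2 + (mm$sd - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-10)
    abort_invalid(sprintf(
      "no truncated normal on [%g, %g] attains mean %g, sd %g", lo, hi, mean, sd))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lo = lo, hi = hi)
}

rtnorm <- function(n, tn) {
  a <- stats::pnorm((tn$lo - tn$mu) / tn$sigma)
  b <- stats::pnorm((tn$hi - tn$mu) / tn$sigma)
  tn$mu + tn$sigma * stats::qnorm(a + stats::runif(n) * (b - a))
}

tnorm_median <- function(tn) {
  a <- stats::pnorm((tn$lo - tn$mu) / tn$sigma)
  b <- stats::pnorm((tn$hi - tn$mu) / tn$sigma)
  tn$mu + tn$sigma * stats::qnorm((a + b) / 2)
}

# Beta(a, b) with a + b = kappa whose median equals m: the hindered
# share of 1 - f1 is strongly right-skewed (many near-zero values with a
# heavy upper tail), which a low-concentration median-matched Beta
# reproduces; matching the mean instead would concentrate essentially all
# mass at zero.
beta_from_median <- function(m, kappa) {
  if (m <= 0 || m >= 1) abort_invalid("median ratio must lie strictly in (0, 1)")
  f <- function(a) suppressWarnings(stats::qbeta(0.5, a, kappa - a)) - m
  a <- stats::uniroot(f, c(1e-8, kappa - 1e-8), tol = 1e-12)$root
  c(a = a, b = kappa - a)
}

# Log-normal parameterized by median and IQR: mu = log(median),
# sigma = (log q3 - log q1) / (2 * qnorm(0.75)).
lnorm_from_quartiles <- function(median, q1, q3) {
  if (any(c(median, q1, q3) <= 0) || q1 >= q3 || median < q1 || median > q3)
    abort_invalid("log-normal spec needs 0 < q1 <= median <= q3")
  list(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Default two-group cohort distribution specification
#'
#' Per-group generator families and parameters for a synthetic SCC vs AC
#' cohort, calibrated to published group summaries: age, restricted
#' fraction f1 and ADC are (truncated, moment-matched) normal; lesion
#' diameter and SUVmax are log-normal matched to the printed median and
#' IQR; sex and smoking are Bernoulli with the printed group rates. The
#' hindered/free split of the remaining fraction 1 - f1 is a Beta draw
#' whose median matches the printed f2:f3 median ratio (concentration
#' `kappa`); f1 + f2 + f3 = 1 then holds exactly per patient.
#'
#' @param kappa Concentration (a + b) of the Beta split of 1 - f1; the
#'   default 1.5 gives the heavy right skew the published hindered
#'   fraction quartiles show.
#' @return A `cohort_spec` list with `SCC` and `AC` sublists.
#' @details Fraction parameters are stored in natural units (0-1); ADC in
#'   mm^2/s. Report layers rescale for display.
#' @export
default_cohort_spec <- function(kappa = 1.5) {
  grp <- function(age_mean, age_sd, male_p, smoking_p,
                  diam, suv, f1_mean, f1_sd, adc_mean, adc_sd, f2f3) {
    list(age = list(mean = age_mean, sd = age_sd),
         male_p = male_p, smoking_p = smoking_p,
         diameter = diam, suvmax = suv,
         f1 = list(mean = f1_mean, sd = f1_sd, lo = 0, hi = 1),
         adc = list(mean = adc_mean, sd = adc_sd, lo = 0, hi = Inf),
         f2_share = f2f3[1] / sum(f2f3))
  }
  structure(list(
    SCC = grp(62.47, 8.85, 25 / 30, 21 / 30,
              list(median = 3.45, q1 = 2.38, q3 = 4.50),
              list(median = 9.93, q1 = 5.30, q3 = 12.80),
              0.6711, 0.1727, 1.11e-3, 0.35e-3, c(8.71, 21.39)),
    AC  = grp(61.51, 8.01, 40 / 67, 21 / 67,
              list(median = 2.00, q1 = 1.50, q3 = 3.00),
              list(median = 3.77, q1 = 1.88, q3 = 6.64),
              0.8627, 0.1301, 1.37e-3, 0.25e-3, c(0.24, 8.32)),
    kappa = kappa), class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec") || !all(c("SCC", "AC") %in% names(spec)))
    abort_invalid("spec must be a cohort_spec with SCC and AC groups")
  for (g in c("SCC", "AC")) {
    s <- spec[[g]]
    if (s$male_p < 0 || s$male_p > 1 || s$smoking_p < 0 || s$smoking_p > 1)
      abort_invalid("Bernoulli rates must lie in [0, 1]")
    if (s$age$sd <= 0 || s$f1$sd <= 0 || s$adc$sd <= 0)
      abort_invalid("standard deviations must be positive")
    if (s$f2_share < 0 || s$f2_share > 1)
      abort_invalid("f2 share of 1 - f1 must lie in [0, 1]")
  }
  if (spec$kappa <= 0) abort_invalid("Beta concentration kappa must be positive")
  invisible(spec)
}

draw_group <- function(n, s, kappa, group) {
  tn_f1 <- tnorm_match(s$f1$mean, s$f1$sd, s$f1$lo, s$f1$hi)
  tn_adc <- tnorm_match(s$adc$mean, s$adc$sd, s$adc$lo, s$adc$hi)
  ld <- lnorm_from_quartiles(s$diameter$median, s$diameter$q1, s$diameter$q3)
  ls <- lnorm_from_quartiles(s$suvmax$median, s$suvmax$q1, s$suvmax$q3)
  f1 <- rtnorm(n, tn_f1)
  ab <- beta_from_median(s$f2_share, kappa)
  r <- stats::rbeta(n, ab["a"], ab["b"])
  data.frame(
    subtype = factor(rep(group, n), levels = c("AC", "SCC")),
    age = stats::rnorm(n, s$age$mean, s$age$sd),
    sex = factor(ifelse(stats::runif(n) < s$male_p, "male", "female"),
                 levels = c("female", "male")),
    smoking = as.integer(stats::runif(n) < s$smoking_p),
    diameter = stats::rlnorm(n, ld$mu, ld$sigma),
    suvmax = stats::rlnorm(n, ls$mu, ls$sigma),
    adc = rtnorm(n, tn_adc),
    f1 = f1,
    f2 = r * (1 - f1),
    f3 = (1 - r) * (1 - f1),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic two-group NSCLC cohort
#'
#' Draws per-patient records for an SCC group and an AC group from the
#' distribution spec. In `"summary"` mode ADC is drawn from its own
#' (truncated normal) generator, independent of the fractions — fast, for
#' statistical testing. In `"image"` mode each patient's imaging columns
#' (ADC, f1, f2, f3) come from fitting a small simulated lesion phantom
#' whose ground-truth fractions were drawn from the same generators, so
#' ADC is physically consistent with the tri-exponential signal.
#'
#' @param n_scc,n_ac Group sizes (each >= 2).
#' @param spec A cohort distribution spec, see [default_cohort_spec()].
#' @param seed Optional integer seed.
#' @param mode `"summary"` (default) or `"image"`.
#' @param snr Image-mode signal-to-noise ratio S0 / sigma at b = 0.
#' @return A data frame (one row per patient) with columns `id`,
#'   `subtype`, `age`, `sex`, `smoking`, `diameter` (cm), `suvmax`
#'   (g/cm^3), `adc` (mm^2/s), `f1`, `f2`, `f3`.
#' @examples
#' cohort <- generate_cohort(30, 67, seed = 1)
#' table(cohort$subtype)
#' @export
generate_cohort <- function(n_scc, n_ac, spec = default_cohort_spec(),
                            seed = NULL, mode = c("summary", "image"),
                            snr = 50) {
  mode <- match.arg(mode)
  validate_cohort_spec(spec)
  if (n_scc < 2 || n_ac < 2) abort_invalid("each group needs at least 2 patients")
  if (!is.null(seed)) set.seed(seed)
  tab <- rbind(draw_group(n_scc, spec$SCC, spec$kappa, "SCC"),
               draw_group(n_ac, spec$AC, spec$kappa, "AC"))
  tab <- cbind(id = sprintf("P%03d", seq_len(nrow(tab))), tab)
  if (mode == "image") {
    sched <- bvalue_schedule()
    S0 <- 100
    for (i in seq_len(nrow(tab))) {
      truth <- compartment_params(tab$f1[i], tab$f2[i], tab$f3[i], S0 = S0)
      ph <- generate_phantom(phantom_spec(
        shape = c(9, 9), center = c(5, 5), axes = c(3, 3),
        truth = truth, sigma = S0 / snr, schedule = sched))
      maps <- fit_parameter_maps(ph$stack, sched, mask = ph$roi_mask)
      sm <- summarize_roi(maps, ph$roi_mask, roi_id = tab$id[i])
      tab$adc[i] <- sm$ADC
      tab$f1[i] <- sm$f1; tab$f2[i] <- sm$f2; tab$f3[i] <- sm$f3
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Build a cohort by simulating and fitting one phantom per patient
#'
#' End-to-end "image mode": for each patient a phantom is generated from
#' its spec, parameter maps are fitted, ROI means extracted, and clinical
#' covariates drawn from that patient's group distribution. Patients whose
#' lesion cannot be fitted are dropped with a warning.
#'
#' @param phantoms List of [phantom_spec()] objects, one per patient.
#' @param groups Character vector of group labels (`"SCC"`/`"AC"`), one
#'   per phantom.
#' @param spec Cohort distribution spec for the clinical covariates.
#' @param seed Optional integer seed.
#' @return A cohort data frame as in [generate_cohort()].
#' @export
cohort_from_phantoms <- function(phantoms, groups,
                                 spec = default_cohort_spec(), seed = NULL) {
  if (length(phantoms) != length(groups))
    abort_invalid("need one group label per phantom spec")
  if (!all(groups %in% c("SCC", "AC")))
    abort_invalid("group labels must be 'SCC' or 'AC'")
  validate_cohort_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(phantoms))
  for (i in seq_along(phantoms)) {
    clin <- draw_group(1, spec[[groups[i]]], spec$kappa, groups[i])
    ph <- generate_phantom(phantoms[[i]])
    sm <- tryCatch({
      maps <- fit_parameter_maps(ph$stack, ph$schedule, mask = ph$roi_mask)
      summarize_roi(maps, ph$roi_mask, roi_id = sprintf("P%03d", i))
    }, rsilung_empty_roi = function(e) NULL)
    if (is.null(sm)) {
      warning(sprintf("patient %d dropped: lesion unfittable", i))
      next
    }
    clin$id <- sm$roi_id
    clin$adc <- sm$ADC; clin$f1 <- sm$f1; clin$f2 <- sm$f2; clin$f3 <- sm$f3
    rows[[i]] <- clin
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[, c("id", "subtype", "age", "sex", "smoking", "diameter",
                 "suvmax", "adc", "f1", "f2", "f3")]
  rownames(out) <- NULL
  out
}
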