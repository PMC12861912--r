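#' Configuration for an end-to-end pipeline run
#'
#' @param seed Integer seed controlling every random stage.
#' @param mode Cohort generation mode, `"summary"` or `"image"`.
#' @param n_scc,n_ac Group sizes.
#' @param candidates Candidate predictors for the univariate screen.
#' @param elimination Multivariate entry strategy, `"none"` or
#'   `"backward"`.
#' @param bootstrap_B Bootstrap resamples for internal validation.
#' @param out_dir Output directory for the report bundle.
#' @param spec_path Optional JSON file overriding the default cohort
#'   distribution spec (must exist if given).
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1, mode = c("summary", "image"),
                       n_scc = 30, n_ac = 67,
                       candidates = c("age", "sex", "smoking", "diameter",
                                      "f1", "f2", "f3", "adc", "suvmax"),
                       elimination = c("none", "backward"),
                       bootstrap_B = 1000, out_dir = tempfile("rsilung_run_"),
                       spec_path = NULL) {
  mode <- match.arg(mode)
  elimination <- match.arg(elimination)
  if (bootstrap_B < 1) abort_invalid("bootstrap_B must be >= 1")
  if (!is.null(spec_path) && !file.exists(spec_path))
    abort_invalid(sprintf("distribution spec file not found: %s", spec_path))
  structure(list(seed = as.integer(seed), mode = mode, n_scc = n_scc,
                 n_ac = n_ac, candidates = candidates,
                 elimination = elimination, bootstrap_B = bootstrap_B,
                 out_dir = out_dir, spec_path = spec_path),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path Path to a JSON file whose keys mirror [run_config()]
#'   arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("config file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

load_cohort_spec <- function(path) {
  if (is.null(path)) return(default_cohort_spec())
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- default_cohort_spec()
  for (g in intersect(names(raw), c("SCC", "AC")))
    spec[[g]] <- utils::modifyList(spec[[g]], raw[[g]])
  if (!is.null(raw$kappa)) spec$kappa <- raw$kappa
  validate_cohort_spec(spec)
  spec
}

write_num_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
}

#' Run the full simulate / fit / analyze / report pipeline
#'
#' Generates a synthetic two-group cohort, produces the group-comparison
#' table, runs the univariate logistic screen, fits the multivariate
#' (combined) model, computes per-predictor and combined ROC analyses with
#' DeLong comparisons against the combined model, performs bootstrap
#' internal validation, and writes calibration and decision-curve tables.
#' All outputs land in `config$out_dir` together with a manifest recording
#' the seed and configuration; identical configuration and seed produce a
#' byte-identical bundle.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results (`cohort`,
#'   `descriptive`, `univariate`, `multivariate`, `roc`, `delong`,
#'   `validation`, `calibration`, `dca`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- load_cohort_spec(config$spec_path)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    cohort <- generate_cohort(config$n_scc, config$n_ac, spec = spec,
                              seed = config$seed, mode = config$mode)

    stage <- "descriptive"
    desc <- descriptive_table(cohort)

    stage <- "univariate"
    uni <- univariate_screen(cohort, config$candidates)
    passed <- uni$predictor[uni$pass]
    if (!length(passed))
      abort("no candidate passed the univariate screen",
            class = "rsilung_empty_screen")

    stage <- "multivariate"
    # The three volume fractions sum to 1, so if all of f1, f2, f3 pass
    # the screen the joint design is singular with the intercept; aliased
    # predictors are dropped one at a time and recorded.
    entry <- passed
    dropped_collinear <- character(0)
    mv <- NULL
    while (is.null(mv)) {
      mv <- tryCatch(
        multivariate_fit(cohort, entry, elimination = config$elimination),
        rsilung_collinearity = function(e) {
          bad <- intersect(entry, strsplit(sub(".*: ", "", conditionMessage(e)),
                                           ", ")[[1]])
          if (!length(bad)) stop(e)
          dropped_collinear <<- c(dropped_collinear, bad)
          entry <<- setdiff(entry, bad)
          NULL
        })
    }
    mv_tab <- data.frame(predictor = names(mv$coefficients),
                         coef = unname(mv$coefficients), se = unname(mv$se),
                         or = unname(mv$or), ci_low = mv$ci[, "low"],
                         ci_high = mv$ci[, "high"], p = unname(mv$p))

    stage <- "roc"
    pos <- binary_outcome(cohort$subtype, "SCC") == 1
    xf <- predictor_frame(cohort, config$candidates)
    roc_rows <- list(); delong_rows <- list()
    combined <- roc_analysis(mv$fitted, pos, direction = ">")
    for (v in names(xf)) {
      r <- roc_analysis(xf[[v]], pos, direction = "auto")
      sc_oriented <- if (r$direction == "<") -xf[[v]] else xf[[v]]
      dl <- delong_test(mv$fitted, sc_oriented, pos)
      roc_rows[[v]] <- data.frame(
        variable = v, auc = r$auc, ci_low = r$ci[1], ci_high = r$ci[2],
        cutoff = r$cutoff, direction = r$direction,
        sensitivity = r$sensitivity, specificity = r$specificity)
      delong_rows[[v]] <- data.frame(variable = v, delta_auc = dl$delta,
                                     z = dl$z, p = dl$p)
    }
    roc_rows$combined <- data.frame(
      variable = "combined", auc = combined$auc, ci_low = combined$ci[1],
      ci_high = combined$ci[2], cutoff = combined$cutoff, direction = ">",
      sensitivity = combined$sensitivity, specificity = combined$specificity)
    roc_tab <- do.call(rbind, roc_rows); rownames(roc_tab) <- NULL
    delong_tab <- do.call(rbind, delong_rows); rownames(delong_tab) <- NULL

    stage <- "validation"
    val <- bootstrap_validate(cohort, mv$retained, B = config$bootstrap_B,
                              seed = config$seed + 1L)

    stage <- "calibration"
    cal <- calibration_curve(mv$fitted, pos)
    dca <- decision_curve(mv$fitted, pos)

    stage <- "report"
    cohort_out <- cohort
    cohort_out$f1 <- cohort$f1 * 100; cohort_out$f2 <- cohort$f2 * 100
    cohort_out$f3 <- cohort$f3 * 100; cohort_out$adc <- cohort$adc * 1000
    write_num_csv(cohort_out, file.path(config$out_dir, "cohort.csv"))
    write_num_csv(desc, file.path(config$out_dir, "descriptive.csv"))
    write_num_csv(uni, file.path(config$out_dir, "univariate.csv"))
    write_num_csv(mv_tab, file.path(config$out_dir, "multivariate.csv"))
    write_num_csv(roc_tab, file.path(config$out_dir, "roc.csv"))
    write_num_csv(delong_tab, file.path(config$out_dir, "delong.csv"))
    write_num_csv(cal$points, file.path(config$out_dir, "calibration.csv"))
    write_num_csv(dca, file.path(config$out_dir, "dca.csv"))
    val_out <- val
    jsonlite::write_json(val_out, file.path(config$out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest <- list(
      seed = config$seed, mode = config$mode,
      n_scc = config$n_scc, n_ac = config$n_ac,
      candidates = config$candidates, elimination = config$elimination,
      bootstrap_B = config$bootstrap_B,
      dropped_collinear = dropped_collinear,
      retained_predictors = mv$retained,
      package_version = as.character(utils::packageVersion("rsilung")))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(cohort = cohort, descriptive = desc, univariate = uni,
         multivariate = mv, multivariate_table = mv_tab, roc = roc_tab,
         delong = delong_tab, validation = val, calibration = cal,
         dca = dca, manifest = manifest)
  }, rsilung_error = function(e) {
    jsonlite::write_json(
      list(failed_stage = stage, message = conditionMessage(e)),
      file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
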