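#' Run the full model-development pipeline on a synthetic cohort
#'
#' Binds the development steps in order: simulate a model-driven cohort,
#' screen predictors with the adaptive LASSO, fit the final euploid-per-MII
#' logistic model and the three intermediate stage models, fit the
#' negative-binomial count model for euploid blastocysts per patient, validate
#' the final model by the holdout method, and summarise the yearly effect size
#' of female age for both sperm groups from the refitted coefficients.
#'
#' The run is a pure function of `(config, seed)`; all seeds are logged in
#' the report. When `out_dir` is given, the report is written as JSON and a
#' small markdown summary alongside.
#'
#' @param n_patients cohort size (ignored when `config` is supplied).
#' @param seed integer seed driving every stochastic step.
#' @param config optional [cohort_config()]; defaults to the calibrated
#'   model-driven configuration with 9 noise covariates for the selection
#'   pool.
#' @param out_dir optional output directory.
#' @return An object of class `art_report` (a nested list).
#' @export
run_pipeline <- function(n_patients = 5000L, seed, config = NULL,
                         out_dir = NULL) {
  if (missing(seed)) abort_input("an explicit integer seed is required")
  if (is.null(config)) {
    config <- cohort_config(n_patients, seed = seed,
                            stage_mode = "MODEL_DRIVEN", n_noise = 9L)
  }
  sim <- sample_cohort(config)
  cohort <- sim$cohort

  pool_cohort <- add_design_columns(cohort, 38.9066)
  pool_cohort$male_age_c <- pool_cohort$male_age - mean(pool_cohort$male_age)
  candidates <- c("ej", "age_c", "ej_age", "male_age_c", "female_bmi",
                  "male_bmi", "infertility_duration", "afc", "amh",
                  grep("^noise", names(cohort), value = TRUE))
  sel <- adaptive_lasso_select(pool_cohort, response = "n_euploid",
                               denominator = "n_mii", candidates = candidates)

  fits <- suppressWarnings(list(
    EUPLOID_PER_MII   = fit_stage_logistic(cohort, "EUPLOID_PER_MII"),
    TWO_PN_PER_MII    = fit_stage_logistic(cohort, "TWO_PN_PER_MII"),
    BLAST_PER_2PN     = fit_stage_logistic(cohort, "BLAST_PER_2PN"),
    EUPLOID_PER_BLAST = fit_stage_logistic(cohort, "EUPLOID_PER_BLAST")
  ))
  nb <- suppressWarnings(
    fit_negative_binomial(pool_cohort, predictors = c("ej", "age_c"),
                          response = "n_euploid"))

  val_seed <- config$seed + 1L
  val <- holdout_validate(cohort, "EUPLOID_PER_MII", seed = val_seed)

  fitted_coefs <- as_coefficients(fits$EUPLOID_PER_MII)
  red_ej <- yearly_reduction(fitted_coefs, "EJACULATE_LIKE")
  red_noa <- yearly_reduction(fitted_coefs, "TESTICULAR_NOA")

  fit_summary <- function(f) {
    list(coefficients = as.list(f$coefficients),
         se = as.list(stats::setNames(sqrt(diag(f$vcov)),
                                      names(f$coefficients))),
         loglik = f$loglik, aic = f$aic, aicc = f$aicc, n_obs = f$n_obs)
  }
  report <- structure(list(
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("artcalc")),
    seeds = list(cohort = config$seed, holdout = val_seed),
    config = list(n_patients = config$n_patients,
                  stage_mode = config$stage_mode,
                  heterogeneity = config$heterogeneity,
                  n_noise = config$n_noise),
    selection = list(candidates = sel$candidates, selected = sel$selected,
                     lambda_chosen = sel$lambda_chosen, gamma = sel$gamma),
    stage_fits = lapply(fits, fit_summary),
    negative_binomial = c(fit_summary(nb), list(dispersion = nb$dispersion)),
    validation = list(train_fraction = val$train_fraction,
                      auc_train = val$auc_train,
                      auc_validation = val$auc_validation),
    effect_size = list(
      ejaculate_overall_yearly_reduction_pct = red_ej$overall_reduction_pct,
      testicular_noa_overall_yearly_reduction_pct = red_noa$overall_reduction_pct)
  ), class = "art_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "pipeline_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report_markdown(report),
               file.path(out_dir, "pipeline_report.md"))
  }
  report
}

report_markdown <- function(r) {
  c("# Model-development pipeline report",
    "",
    sprintf("- generated: %s (artcalc %s)", r$generated, r$package_version),
    sprintf("- cohort: %d patients, %s mode, seeds cohort=%d holdout=%d",
            r$config$n_patients, r$config$stage_mode,
            r$seeds$cohort, r$seeds$holdout),
    sprintf("- adaptive LASSO selected: %s",
            paste(r$selection$selected, collapse = ", ")),
    sprintf("- holdout AUC: train %.4f, validation %.4f",
            r$validation$auc_train, r$validation$auc_validation),
    sprintf("- NB dispersion: %.4f", r$negative_binomial$dispersion),
    sprintf("- overall yearly reduction in p (fitted model): %.2f%% (ejaculate), %.2f%% (testicular-NOA)",
            r$effect_size$ejaculate_overall_yearly_reduction_pct,
            r$effect_size$testicular_noa_overall_yearly_reduction_pct))
}

#' @export
print.art_report <- function(x, ...) {
  cat(paste(report_markdown(x), collapse = "\n"), "\n")
  invisible(x)
}
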