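#' Stage specifications for per-oocyte binary responses
#'
#' Maps each embryonic stage response to its numerator and denominator count
#' columns: euploid blastocyst per MII oocyte (the final model response), 2PN
#' zygote per MII oocyte, blastocyst per 2PN zygote, and euploid blastocyst
#' per biopsied blastocyst.
#'
#' @param stage one of `"EUPLOID_PER_MII"`, `"TWO_PN_PER_MII"`,
#'   `"BLAST_PER_2PN"`, `"EUPLOID_PER_BLAST"`.
#' @return A list with `stage`, `numerator`, `denominator`.
#' @export
stage_spec <- function(stage = c("EUPLOID_PER_MII", "TWO_PN_PER_MII",
                                 "BLAST_PER_2PN", "EUPLOID_PER_BLAST")) {
  stage <- match.arg(stage)
  map <- list(
    EUPLOID_PER_MII  = c("n_euploid", "n_mii"),
    TWO_PN_PER_MII   = c("n_2pn", "n_mii"),
    BLAST_PER_2PN    = c("n_blast", "n_2pn"),
    EUPLOID_PER_BLAST = c("n_euploid", "n_blast")
  )[[stage]]
  list(stage = stage, numerator = map[1], denominator = map[2])
}

# add the published-model design columns to a cohort table
add_design_columns <- function(cohort, A0) {
  grp <- classify_group_vec(cohort$sperm_source, cohort$azoospermia_type)
  ej <- as.numeric(grp == "EJACULATE_LIKE")
  ac <- cohort$female_age - A0
  cohort$ej <- ej
  cohort$ej_age <- ej * ac
  cohort$noa_age <- (1 - ej) * ac
  cohort$age_c <- ac
  cohort
}

aicc_from <- function(aic, k, n) aic + 2 * k * (k + 1) / (n - k - 1)

new_art_fit <- function(coefficients, vcov, loglik, n_obs, family, link,
                        model = NULL, dispersion = NULL, extra = list()) {
  k <- length(coefficients) + if (identical(family, "negative_binomial")) 1L else 0L
  aic <- -2 * loglik + 2 * k
  structure(
    c(list(coefficients = coefficients, vcov = vcov, loglik = loglik,
           aic = aic, aicc = aicc_from(aic, k, n_obs), n_obs = n_obs,
           n_par = k, family = family, link = link, model = model,
           dispersion = dispersion), extra),
    class = "art_fit"
  )
}

#' @export
print.art_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s link), %d observations\n", x$family, x$link, x$n_obs))
  print(round(cbind(estimate = x$coefficients,
                    se = sqrt(diag(x$vcov))), 6))
  cat(sprintf("  loglik %.3f  AIC %.2f  AICc %.2f\n", x$loglik, x$aic, x$aicc))
  if (!is.null(x$dispersion)) {
    cat(sprintf("  overdispersion %.4f\n", x$dispersion))
  }
  invisible(x)
}

#' Aggregated-binomial logistic fit of a stage response
#'
#' Maximises the aggregated binomial log-likelihood
#' \deqn{\sum_i [k_i \log p_i + (m_i - k_i)\log(1 - p_i)]}
#' with logit link, where `k_i`/`m_i` are the stage numerator/denominator
#' counts for patient `i`. This is likelihood-equivalent to expanding each
#' oocyte to a Bernoulli row. The default design mirrors the published model:
#' an ejaculate-like group indicator plus group-specific centred-age slopes,
#' with coefficients reported as `(a, b, c, d)`. Alternatively any numeric
#' cohort columns can be supplied as predictors (intercept always included;
#' `character(0)` gives the intercept-only fit, whose MLE is
#' `logit(sum(k)/sum(m))`).
#'
#' @param cohort a cohort data frame (see [validate_cohort()]).
#' @param stage a [stage_spec()] or stage name.
#' @param predictors `NULL` for the published-model design, or a character
#'   vector of numeric cohort columns.
#' @param A0 centering age used by the default design.
#' @return An `art_fit` with coefficients, covariance (inverse observed
#'   information), log-likelihood, AIC/AICc (`n` = number of Bernoulli
#'   trials) and the underlying [stats::glm] object.
#' @export
fit_stage_logistic <- function(cohort, stage = "EUPLOID_PER_MII",
                               predictors = NULL, A0 = 38.9066) {
  validate_cohort(cohort)
  if (is.character(stage)) stage <- stage_spec(stage)
  k <- cohort[[stage$numerator]]
  m <- cohort[[stage$denominator]]
  keep <- m > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-denominator rows dropped", call. = FALSE)
    cohort <- cohort[keep, , drop = FALSE]
    k <- k[keep]; m <- m[keep]
  }
  if (nrow(cohort) < 2) abort_input("too few rows with positive denominators")

  if (is.null(predictors)) {
    cohort <- add_design_columns(cohort, A0)
    rhs <- c("ej", "ej_age", "noa_age")
    coef_names <- c("a", "b", "c", "d")
  } else if (length(predictors) == 0) {
    rhs <- character(0)
    coef_names <- "(Intercept)"
  } else {
    miss <- setdiff(predictors, names(cohort))
    if (length(miss)) {
      abort_input("unknown predictor columns: ", paste(miss, collapse = ", "))
    }
    rhs <- predictors
    coef_names <- c("(Intercept)", predictors)
  }
  fml <- stats::reformulate(if (length(rhs)) rhs else "1",
                            response = quote(cbind(k, m - k)))
  dat <- cbind(cohort, k = k, m = m)
  fit <- stats::glm(fml, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 200))
  if (!fit$converged) abort_input("logistic fit did not converge")
  mu <- stats::fitted(fit)
  if (any(abs(stats::coef(fit)) > 15) &&
      (any(mu < 1e-10) || any(mu > 1 - 1e-10))) {
    abort_input("complete separation detected: a predictor perfectly splits ",
                "the stage outcome; remove or merge it")
  }
  cf <- stats::coef(fit)
  names(cf) <- coef_names
  V <- stats::vcov(fit)
  dimnames(V) <- list(coef_names, coef_names)
  new_art_fit(cf, V, loglik = as.numeric(stats::logLik(fit)),
              n_obs = sum(m), family = "binomial", link = "logit",
              model = fit,
              extra = list(stage = stage$stage, A0 = A0,
                           default_design = is.null(predictors)))
}

#' Export a fitted published-design model as coefficients
#'
#' Converts a default-design [fit_stage_logistic()] result into an
#' [art_coefficients()] object, carrying the full fitted covariance so that
#' downstream confidence limits use it exactly.
#'
#' @param fit an `art_fit` from the default design.
#' @param source provenance note.
#' @return An `art_coefs` object.
#' @export
as_coefficients <- function(fit, source = "fitted in artcalc") {
  stopifnot(inherits(fit, "art_fit"))
  if (!isTRUE(fit$default_design)) {
    abort_input("only default-design stage fits map onto (a, b, c, d)")
  }
  se <- sqrt(diag(fit$vcov))
  art_coefficients(a = fit$coefficients[["a"]], b = fit$coefficients[["b"]],
                   c = fit$coefficients[["c"]], d = fit$coefficients[["d"]],
                   A0 = fit$A0,
                   se = c(a = se[[1]], b = se[[2]], c = se[[3]], d = se[[4]]),
                   covariance = fit$vcov, source = source)
}

#' Negative-binomial model for per-patient euploid counts
#'
#' Fits a negative-binomial GLM with log mean link to the number of euploid
#' blastocysts per patient, with a single constant overdispersion parameter
#' estimated jointly by maximum likelihood on its own (identity) scale. The
#' reported `dispersion` is `1/theta` in the usual NB2 parameterisation
#' (`Var = mu + dispersion * mu^2`), so 0 is the Poisson boundary.
#'
#' @param cohort a cohort data frame.
#' @param predictors character vector of numeric cohort columns (empty for
#'   intercept-only).
#' @param response count column, default `n_euploid`.
#' @return An `art_fit` with `family = "negative_binomial"`, the `dispersion`
#'   estimate, `theta` and `se_log_theta` in the extras.
#' @export
fit_negative_binomial <- function(cohort, predictors = character(0),
                                  response = "n_euploid") {
  validate_cohort(cohort)
  miss <- setdiff(predictors, names(cohort))
  if (length(miss)) {
    abort_input("unknown predictor columns: ", paste(miss, collapse = ", "))
  }
  fml <- stats::reformulate(if (length(predictors)) predictors else "1",
                            response = response)
  boundary <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      MASS::glm.nb(fml, data = cohort, control = stats::glm.control(maxit = 100)),
      error = function(e) e),
    warning = function(w) {
      # glm.nb warns while theta diverges, i.e. dispersion collapses to 0
      if (grepl("iteration limit|theta|truncated at zero|NaNs produced",
                conditionMessage(w), ignore.case = TRUE)) {
        boundary <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (inherits(fit, "error")) {
    # theta divergence can abort glm.nb outright; if a Poisson fit shows no
    # overdispersion the ML solution is on the boundary, otherwise fail
    pfit <- stats::glm(fml, data = cohort, family = stats::poisson())
    pearson <- sum(stats::residuals(pfit, "pearson")^2) /
      stats::df.residual(pfit)
    if (pearson > 1.05) {
      abort_input("negative-binomial fit failed: ", conditionMessage(fit))
    }
    warning("dispersion estimate at the Poisson boundary (~0): counts are ",
            "not overdispersed", call. = FALSE)
    return(new_art_fit(stats::coef(pfit), stats::vcov(pfit),
                       loglik = as.numeric(stats::logLik(pfit)),
                       n_obs = nrow(cohort), family = "negative_binomial",
                       link = "log", model = pfit, dispersion = 0,
                       extra = list(theta = Inf, se_log_theta = NA_real_,
                                    response = response)))
  }
  theta <- fit$theta
  disp <- 1 / theta
  if (boundary || disp < 1e-4) {
    warning("dispersion estimate at the Poisson boundary (~0): counts are ",
            "not overdispersed", call. = FALSE)
  }
  cf <- stats::coef(fit)
  new_art_fit(cf, stats::vcov(fit),
              loglik = as.numeric(stats::logLik(fit)),
              n_obs = nrow(cohort), family = "negative_binomial", link = "log",
              model = fit, dispersion = disp,
              extra = list(theta = theta, se_log_theta = fit$SE.theta / theta,
                           response = response))
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' Computes the AUC as the tie-corrected Mann-Whitney statistic: the fraction
#' of (positive, negative) score pairs that are concordant, counting ties as
#' one half.
#'
#' @param scores numeric prediction scores.
#' @param outcomes binary outcomes (0/1 or logical).
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, outcomes) {
  outcomes <- as.numeric(outcomes)
  if (length(scores) != length(outcomes) || anyNA(scores) || anyNA(outcomes)) {
    abort_input("scores and outcomes must be equal-length and complete")
  }
  if (!all(outcomes %in% c(0, 1))) abort_input("outcomes must be binary")
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) abort_input("both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# expand aggregated per-patient counts into per-oocyte (score, outcome) pairs
expand_oocyte_pairs <- function(score, k, m) {
  list(scores = rep(score, m),
       outcomes = unlist(lapply(seq_along(k), function(i) {
         c(rep(1, k[i]), rep(0, m[i] - k[i]))
       }), use.names = FALSE))
}

#' Holdout validation of a stage fit
#'
#' Randomly partitions the cohort into training (default 80%) and validation
#' sets, fits on the training set, and reports the per-oocyte ROC AUC on both
#' sets, computed from expanded (score, outcome) pairs where each oocyte
#' carries its patient's predicted stage probability.
#'
#' @param cohort a cohort data frame.
#' @param stage stage name or [stage_spec()].
#' @param predictors as in [fit_stage_logistic()].
#' @param train_fraction fraction of patients used for fitting.
#' @param seed mandatory RNG seed for the split (logged in the result).
#' @return A list of class `art_validation` with `train_fraction`, `seed`,
#'   `auc_train`, `auc_validation`, split sizes and the training fit.
#' @export
holdout_validate <- function(cohort, stage = "EUPLOID_PER_MII",
                             predictors = NULL, train_fraction = 0.8, seed) {
  validate_cohort(cohort)
  if (missing(seed)) abort_input("an explicit seed is required for the split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_input("train_fraction must be in (0,1)")
  }
  if (is.character(stage)) stage <- stage_spec(stage)
  set.seed(seed)
  n <- nrow(cohort)
  idx_train <- sort(sample.int(n, size = floor(train_fraction * n)))
  idx_val <- setdiff(seq_len(n), idx_train)
  if (length(idx_val) == 0) abort_input("degenerate split: empty validation set")
  grp <- classify_group_vec(cohort$sperm_source, cohort$azoospermia_type)
  for (idx in list(idx_train, idx_val)) {
    kk <- cohort[[stage$numerator]][idx]
    mm <- cohort[[stage$denominator]][idx]
    if (is.null(predictors) && length(unique(grp[idx])) < 2) {
      abort_input("degenerate split: a partition lacks a sperm-source group")
    }
    if (sum(kk) == 0 || sum(kk) == sum(mm)) {
      abort_input("degenerate split: a partition has a single outcome class")
    }
  }
  fit <- fit_stage_logistic(cohort[idx_train, , drop = FALSE], stage,
                            predictors = predictors)
  score_all <- predict_stage(fit, cohort)
  auc_for <- function(idx) {
    kk <- cohort[[stage$numerator]][idx]
    mm <- cohort[[stage$denominator]][idx]
    pairs <- expand_oocyte_pairs(score_all[idx], kk, mm)
    roc_auc(pairs$scores, pairs$outcomes)
  }
  structure(
    list(train_fraction = train_fraction, seed = seed,
         auc_train = auc_for(idx_train), auc_validation = auc_for(idx_val),
         n_train = length(idx_train), n_validation = length(idx_val),
         fit = fit),
    class = "art_validation"
  )
}

# per-patient predicted stage probability from an art_fit
predict_stage <- function(fit, cohort) {
  stopifnot(inherits(fit, "art_fit"), !is.null(fit$model))
  if (isTRUE(fit$default_design)) cohort <- add_design_columns(cohort, fit$A0)
  as.numeric(stats::predict(fit$model, newdata = cohort, type = "response"))
}

#' @export
print.art_validation <- function(x, ...) {
  cat(sprintf(
    "Holdout validation (train %.0f%%, seed %s): AUC train %.4f, validation %.4f\n",
    100 * x$train_fraction, format(x$seed), x$auc_train, x$auc_validation))
  invisible(x)
}

#' Likelihood importance of female age
#'
#' Compares the full published-design fit (group indicator plus two
#' group-specific age slopes) against the nested age-free fit (group indicator
#' only) on the euploid-per-MII response, returning the log-likelihood
#' difference, the number of dropped slopes (df = 2) and the likelihood-ratio
#' chi-square p-value (`2 * difference ~ chi^2_df`).
#'
#' @param cohort a cohort data frame.
#' @param A0 centering age for the design.
#' @return A list with `loglik_diff`, `df`, `p_value`, and both fits.
#' @export
age_importance <- function(cohort, A0 = 38.9066) {
  validate_cohort(cohort)
  full <- fit_stage_logistic(cohort, "EUPLOID_PER_MII", A0 = A0)
  cohort2 <- add_design_columns(cohort, A0)
  reduced <- fit_stage_logistic(cohort2, "EUPLOID_PER_MII",
                                predictors = "ej")
  diff <- full$loglik - reduced$loglik
  df <- full$n_par - reduced$n_par
  list(loglik_diff = diff, df = df,
       p_value = stats::pchisq(2 * diff, df, lower.tail = FALSE),
       full = full, reduced = reduced)
}

#' Yearly effect size of female age on the per-oocyte euploidy probability
#'
#' The year-over-year effect size is the ratio `p(t+1)/p(t)` of the model
#' probability at consecutive integer ages; the overall yearly reduction is
#' `100 * (1 - geometric mean of the ratios)`, which by telescoping equals
#' `100 * (1 - (p(age_end)/p(age_start))^(1/(age_end - age_start)))`.
#'
#' @param coefs an [art_coefficients()] object.
#' @param group `"EJACULATE_LIKE"` or `"TESTICULAR_NOA"`.
#' @param age_start,age_end integer age range (default 24--45, the range over
#'   which the model was characterised).
#' @param validate logical; `FALSE` permits evaluation outside the clinical
#'   age limits (asymptotic diagnostics).
#' @return A list with `ages`, `p`, `ratios`, `geometric_mean`,
#'   `overall_reduction_pct`.
#' @export
yearly_reduction <- function(coefs = default_coefficients(),
                             group = "EJACULATE_LIKE",
                             age_start = 24L, age_end = 45L, validate = TRUE) {
  group <- resolve_group(group)
  if (abs(age_start - round(age_start)) > 1e-8 ||
      abs(age_end - round(age_end)) > 1e-8 || age_start >= age_end) {
    abort_input("age_start and age_end must be integers with age_start < age_end")
  }
  ages <- seq(as.integer(age_start), as.integer(age_end))
  p <- stats::plogis(linear_predictor(ages, group, coefs, validate = validate))
  if (any(p <= 0) || any(!is.finite(p))) {
    abort_input("probability underflow at extreme ages")
  }
  ratios <- p[-1] / p[-length(p)]
  gm <- exp(mean(log(ratios)))
  list(ages = ages, p = p, ratios = ratios, geometric_mean = gm,
       overall_reduction_pct = 100 * (1 - gm))
}
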