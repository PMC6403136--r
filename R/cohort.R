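#' Synthetic IVF/ICSI cohort generator configuration
#'
#' Describes the study conditions the generator emulates: a PGT-A cohort with
#' mean female age 38.9 years on 24--45, sperm-source mix 71.5% ejaculate /
#' 4.9% epididymis / 23.6% testicle, mean 8.2 oocytes retrieved per patient,
#' 78.1% of them mature (MII), and the per-oocyte stage chain
#' 2PN (67.3%) -> blastocyst (48.9%) -> euploid (34.8% per biopsied
#' blastocyst).
#'
#' Female age is drawn from a Beta distribution scaled to
#' `[age_low, age_high]` and moment-matched to `age_mean`; the default
#' concentration 10 makes the central 95% mass approximate the reported
#' 32.4--42.4 interval. The retrieved-oocyte count is negative binomial with
#' the reported mean and a dispersion (size) of 10, whose central 95% range
#' approximates the reported 2.0--16.2.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer RNG seed; regeneration with the same configuration is
#'   bit-identical.
#' @param age_mean,age_low,age_high,age_concentration scaled-Beta age model.
#' @param source_mix named probabilities over ejaculate / epididymis /
#'   testicle; must sum to 1.
#' @param noa_fraction fraction of testicular-sperm users whose azoospermia is
#'   non-obstructive (default 44/65, the reported NOA share among azoospermic
#'   men).
#' @param retrieved_mean,retrieved_dispersion negative-binomial mean and size
#'   for oocytes retrieved per patient.
#' @param mii_rate per-retrieved-oocyte maturation probability.
#' @param stage_mode `"CONSTANT_RATES"` draws every stage with the constant
#'   probabilities below; `"MODEL_DRIVEN"` draws euploid-per-MII outcomes from
#'   the logistic age/sperm model in `coefficients` (intermediate counts are
#'   drawn conditionally so the count ordering always holds).
#' @param p_2pn,p_blast,p_euploid_blast constant per-stage probabilities
#'   (2PN per MII, blastocyst per 2PN, euploid per biopsied blastocyst).
#' @param coefficients an [art_coefficients()] object for `MODEL_DRIVEN` mode
#'   (defaults to the shipped published model).
#' @param heterogeneity logical; when `TRUE`, each patient's stage
#'   probabilities are Beta-perturbed around their means (Beta-binomial),
#'   inducing marginal overdispersion in the euploid counts. Off by default,
#'   matching the working assumption that stage probabilities are constant
#'   across women.
#' @param concentration Beta concentration of the heterogeneity perturbation
#'   (larger = milder).
#' @param high_dfi_rate marginal probability of a high sperm DNA fragmentation
#'   flag among non-azoospermic men.
#' @param n_noise number of standard-normal noise covariates (`noise1`, ...)
#'   appended for variable-selection experiments.
#' @return An object of class `art_cohort_config`.
#' @export
cohort_config <- function(n_patients, seed,
                          age_mean = 38.9, age_low = 24, age_high = 45,
                          age_concentration = 10,
                          source_mix = c(ejaculate = 0.715,
                                         epididymis = 0.049,
                                         testicle = 0.236),
                          noa_fraction = 44 / 65,
                          retrieved_mean = 8.2, retrieved_dispersion = 10,
                          mii_rate = 0.781,
                          stage_mode = c("CONSTANT_RATES", "MODEL_DRIVEN"),
                          p_2pn = 0.673, p_blast = 0.489,
                          p_euploid_blast = 0.348,
                          coefficients = NULL,
                          heterogeneity = FALSE, concentration = 30,
                          high_dfi_rate = 0.15, n_noise = 0L) {
  stage_mode <- match.arg(stage_mode)
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort_input("n_patients must be a positive integer")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_input("an explicit integer seed is required")
  }
  if (abs(sum(source_mix) - 1) > 1e-8 || any(source_mix < 0)) {
    abort_input("source_mix must be non-negative and sum to 1")
  }
  rates <- c(mii_rate = mii_rate, p_2pn = p_2pn, p_blast = p_blast,
             p_euploid_blast = p_euploid_blast, noa_fraction = noa_fraction,
             high_dfi_rate = high_dfi_rate)
  if (any(rates < 0 | rates > 1)) {
    abort_input("all stage probabilities and fractions must lie in [0,1]")
  }
  if (retrieved_mean <= 0 || retrieved_dispersion <= 0 ||
      age_concentration <= 0 || concentration <= 0) {
    abort_input("means, dispersions and concentrations must be positive")
  }
  if (age_mean <= age_low || age_mean >= age_high) {
    abort_input("age_mean must lie strictly inside [age_low, age_high]")
  }
  if (stage_mode == "MODEL_DRIVEN" && is.null(coefficients)) {
    coefficients <- default_coefficients()
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         age_mean = age_mean, age_low = age_low, age_high = age_high,
         age_concentration = age_concentration,
         source_mix = source_mix, noa_fraction = noa_fraction,
         retrieved_mean = retrieved_mean,
         retrieved_dispersion = retrieved_dispersion,
         mii_rate = mii_rate, stage_mode = stage_mode,
         p_2pn = p_2pn, p_blast = p_blast,
         p_euploid_blast = p_euploid_blast,
         coefficients = coefficients,
         heterogeneity = isTRUE(heterogeneity), concentration = concentration,
         high_dfi_rate = high_dfi_rate, n_noise = as.integer(n_noise)),
    class = "art_cohort_config"
  )
}

# per-patient Beta perturbation of a stage probability (Beta-binomial device)
perturb <- function(p, n, conc, enabled) {
  if (!enabled) return(rep_len(p, n))
  p <- rep_len(p, n)
  ok <- p > 0 & p < 1
  out <- p
  out[ok] <- stats::rbeta(sum(ok), p[ok] * conc, (1 - p[ok]) * conc)
  out
}

#' Simulate a cohort
#'
#' Draws a per-patient covariate set (age, sperm source and azoospermia type,
#' secondary demographics) and the oocyte stage chain
#' retrieved -> MII -> 2PN -> blastocyst -> euploid as sequential binomials,
#' so the count ordering `n_euploid <= n_blast <= n_2pn <= n_mii <=
#' n_retrieved` holds for every patient by construction. In `MODEL_DRIVEN`
#' mode the end-to-end euploid-per-MII probability equals the logistic model
#' value exactly; the intermediate stage probabilities are taken from the
#' constant rates and clamped upward where needed so the chain stays ordered
#' (only relevant at young ages where the model probability exceeds the
#' unconditional blastulation rate).
#'
#' @param config an [cohort_config()] object.
#' @return A list with elements `cohort` (data frame, one row per patient) and
#'   `truth` (configuration echo plus per-patient latent probabilities and the
#'   generating coefficient values).
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "art_cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients

  m01 <- (config$age_mean - config$age_low) / (config$age_high - config$age_low)
  age <- config$age_low + (config$age_high - config$age_low) *
    stats::rbeta(n, m01 * config$age_concentration,
                 (1 - m01) * config$age_concentration)

  source <- sample(names(config$source_mix), n, replace = TRUE,
                   prob = config$source_mix)
  azoo <- rep("none", n)
  azoo[source == "epididymis"] <- "obstructive"
  tes <- source == "testicle"
  is_noa <- tes & stats::runif(n) < config$noa_fraction
  azoo[is_noa] <- "non_obstructive"
  # non-NOA testicular retrievals: mostly obstructive azoospermia, the rest
  # non-azoospermic men with high DNA fragmentation
  tes_oa <- tes & !is_noa & stats::runif(n) < 0.7
  azoo[tes_oa] <- "obstructive"
  high_dfi <- stats::runif(n) < config$high_dfi_rate
  high_dfi[tes & !is_noa & !tes_oa] <- TRUE
  high_dfi[azoo != "none"] <- FALSE

  # secondary demographics (no effect on outcomes; realistic selection pool)
  male_age <- round(age + stats::rnorm(n, 3.5, 4), 1)
  female_bmi <- round(stats::rnorm(n, 24.5, 2.8), 1)
  male_bmi <- round(stats::rnorm(n, 27.6, 2.4), 1)
  infertility_duration <- round(stats::rgamma(n, shape = 4, scale = 7 / 4), 1)
  afc <- stats::rnbinom(n, size = 4, mu = 6.7)
  amh <- round(stats::rlnorm(n, log(1.0), 0.9), 2)
  por_flag <- afc < 5 | amh < 1.2

  retrieved <- as.integer(stats::rnbinom(n, size = config$retrieved_dispersion,
                                         mu = config$retrieved_mean))
  mii <- stats::rbinom(n, retrieved,
                       perturb(config$mii_rate, n, config$concentration,
                               config$heterogeneity))

  group <- classify_group_vec(source, azoo)
  if (config$stage_mode == "CONSTANT_RATES") {
    p2 <- perturb(config$p_2pn, n, config$concentration, config$heterogeneity)
    p3 <- perturb(config$p_blast, n, config$concentration, config$heterogeneity)
    p4 <- perturb(config$p_euploid_blast, n, config$concentration,
                  config$heterogeneity)
    n_2pn <- stats::rbinom(n, mii, p2)
    n_blast <- stats::rbinom(n, n_2pn, p3)
    n_euploid <- stats::rbinom(n, n_blast, p4)
    p_eu_mii <- p2 * p3 * p4
  } else {
    cf <- config$coefficients
    ac <- age - cf$A0
    p_eu_mii <- ifelse(group == "EJACULATE_LIKE",
                       stats::plogis(cf$a + cf$b + cf$c * ac),
                       stats::plogis(cf$a + cf$d * ac))
    p_eu_mii <- perturb(p_eu_mii, n, config$concentration,
                        config$heterogeneity)
    # unconditional per-MII stage probabilities, clamped to stay ordered
    pb <- pmax(config$p_2pn * config$p_blast, p_eu_mii)
    p2u <- pmax(config$p_2pn, pb)
    n_euploid <- stats::rbinom(n, mii, p_eu_mii)
    n_blast <- n_euploid +
      stats::rbinom(n, mii - n_euploid,
                    ifelse(p_eu_mii < 1, (pb - p_eu_mii) / (1 - p_eu_mii), 0))
    n_2pn <- n_blast +
      stats::rbinom(n, mii - n_blast,
                    ifelse(pb < 1, (p2u - pb) / (1 - pb), 0))
  }

  cohort <- data.frame(
    patient_id = seq_len(n),
    female_age = round(age, 2),
    sperm_source = source,
    azoospermia_type = azoo,
    high_dfi = high_dfi,
    male_age = male_age, female_bmi = female_bmi, male_bmi = male_bmi,
    infertility_duration = infertility_duration,
    afc = afc, amh = amh, por_flag = por_flag,
    n_retrieved = retrieved, n_mii = mii, n_2pn = n_2pn,
    n_blast = n_blast, n_euploid = n_euploid,
    stringsAsFactors = FALSE
  )
  if (config$n_noise > 0) {
    noise <- matrix(stats::rnorm(n * config$n_noise), nrow = n,
                    dimnames = list(NULL, paste0("noise", seq_len(config$n_noise))))
    cohort <- cbind(cohort, as.data.frame(noise))
  }
  truth <- list(
    config = config,
    p_euploid_per_mii = p_eu_mii,
    coefficients = if (config$stage_mode == "MODEL_DRIVEN") config$coefficients,
    stage_rates = c(mii = config$mii_rate, p_2pn = config$p_2pn,
                    p_blast = config$p_blast,
                    p_euploid_blast = config$p_euploid_blast)
  )
  list(cohort = cohort, truth = truth)
}

#' Overdispersion report for per-patient euploid counts
#'
#' Summarises the marginal distribution of `n_euploid` across patients: mean,
#' variance, variance/mean ratio, and an intercept-only negative-binomial
#' versus Poisson log-likelihood comparison. A variance/mean ratio above 1
#' together with a higher NB log-likelihood indicates the overdispersion that
#' motivates a negative-binomial count model.
#'
#' @param cohort a cohort data frame.
#' @param min_patients minimum cohort size for a stable report.
#' @return A list with `mean`, `variance`, `ratio`, `loglik_poisson`,
#'   `loglik_nb`, `degenerate` (TRUE when all counts are zero, in which case
#'   `ratio` is `NA`).
#' @export
distribution_check <- function(cohort, min_patients = 500L) {
  validate_cohort(cohort)
  if (nrow(cohort) < min_patients) {
    abort_input("at least ", min_patients, " patients required for a ",
                "distribution check")
  }
  y <- cohort$n_euploid
  m <- mean(y)
  v <- stats::var(y)
  if (all(y == 0)) {
    return(list(mean = 0, variance = 0, ratio = NA_real_,
                loglik_poisson = NA_real_, loglik_nb = NA_real_,
                degenerate = TRUE))
  }
  ll_pois <- as.numeric(stats::logLik(stats::glm(y ~ 1, family = stats::poisson())))
  ll_nb <- tryCatch(
    as.numeric(stats::logLik(suppressWarnings(MASS::glm.nb(y ~ 1)))),
    error = function(e) NA_real_)
  list(mean = m, variance = v, ratio = v / m,
       loglik_poisson = ll_pois, loglik_nb = ll_nb, degenerate = FALSE)
}

.count_cols <- c("n_retrieved", "n_mii", "n_2pn", "n_blast", "n_euploid")

#' Validate a cohort table
#'
#' Checks the schema (required columns, non-negative integer counts) and the
#' per-row stage ordering `n_euploid <= n_blast <= n_2pn <= n_mii <=
#' n_retrieved`; violations are reported with the offending row numbers.
#'
#' @param cohort a cohort data frame.
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    abort_input("no records: cohort table is empty")
  }
  need <- c("patient_id", "female_age", "sperm_source", "azoospermia_type",
            .count_cols)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    abort_input("cohort is missing required columns: ",
                paste(miss, collapse = ", "))
  }
  for (cc in .count_cols) {
    x <- cohort[[cc]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0) ||
        any(abs(x - round(x)) > 1e-8)) {
      abort_input("column ", cc, " must hold non-negative integer counts")
    }
  }
  bad_src <- !cohort$sperm_source %in% c("ejaculate", "epididymis", "testicle")
  if (any(bad_src)) {
    abort_input("invalid sperm_source on rows ",
                paste(utils::head(which(bad_src), 10), collapse = ", "))
  }
  ord <- cbind(cohort$n_euploid <= cohort$n_blast,
               cohort$n_blast <= cohort$n_2pn,
               cohort$n_2pn <= cohort$n_mii,
               cohort$n_mii <= cohort$n_retrieved)
  labs <- c("n_euploid > n_blast", "n_blast > n_2pn",
            "n_2pn > n_mii", "n_mii > n_retrieved")
  for (j in 1:4) {
    if (any(!ord[, j])) {
      abort_input("count ordering violated (", labs[j], ") on rows ",
                  paste(utils::head(which(!ord[, j]), 10), collapse = ", "))
    }
  }
  invisible(cohort)
}

#' Read / write cohort CSV files
#'
#' One row per patient with header-defined columns; [validate_cohort()] is
#' applied on read, with row-level error reporting. A write/read round trip
#' is field-identical.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort()` returns the validated data frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_input("cohort file not found: ", path)
  x <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) abort_input("no records: ", conditionMessage(e)))
  validate_cohort(x)
  x
}
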