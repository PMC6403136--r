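# Shared fixtures built in code.

# published coefficient values, written out independently of the package
# fixture so file/parse errors are detectable
PUB <- list(a = -2.6518, b = 0.2231659, c = -0.2045457, d = -0.1530924,
            A0 = 38.9066,
            se = c(a = 0.1174497, b = 0.1174497, c = 0.0269435, d = 0.0354465))

pub_coefs <- function(se = PUB$se, covariance = NULL) {
  art_coefficients(PUB$a, PUB$b, PUB$c, PUB$d, PUB$A0, se = se,
                   covariance = covariance)
}

# a probability estimate with explicitly chosen CI, for planner tests
fake_estimate <- function(p, ci_low = p, ci_high = p, alpha = 0.05) {
  structure(list(p = p, y = qlogis(p), se_y = NA_real_,
                 ci_low = ci_low, ci_high = ci_high, alpha = alpha,
                 age = NA_real_, group = "EJACULATE_LIKE"),
            class = "art_prob")
}

# minimal hand-built cohort with consistent stage counts
toy_cohort <- function(n = 12, seed = 99) {
  set.seed(seed)
  mii <- sample(3:9, n, replace = TRUE)
  n2 <- rbinom(n, mii, 0.7)
  nb <- rbinom(n, n2, 0.5)
  ne <- rbinom(n, nb, 0.4)
  data.frame(
    patient_id = seq_len(n),
    female_age = round(runif(n, 25, 44), 1),
    sperm_source = sample(c("ejaculate", "testicle"), n, replace = TRUE,
                          prob = c(0.8, 0.2)),
    azoospermia_type = "none",
    high_dfi = FALSE,
    n_retrieved = mii + rpois(n, 2), n_mii = mii, n_2pn = n2,
    n_blast = nb, n_euploid = ne,
    stringsAsFactors = FALSE
  ) |> within(azoospermia_type[sperm_source == "testicle"] <- "non_obstructive")
}

# wrap a count vector in a schema-valid cohort (for count-model tests)
count_cohort <- function(y) {
  data.frame(patient_id = seq_along(y), female_age = 35,
             sperm_source = "ejaculate", azoospermia_type = "none",
             high_dfi = FALSE,
             n_retrieved = y + 2, n_mii = y + 1, n_2pn = y + 1,
             n_blast = y, n_euploid = y)
}

# expand aggregated counts to Bernoulli rows (oracle for likelihood checks)
expand_bernoulli <- function(cohort, num = "n_euploid", den = "n_mii") {
  idx <- rep(seq_len(nrow(cohort)), cohort[[den]])
  out <- cohort[idx, , drop = FALSE]
  out$outcome <- unlist(lapply(seq_len(nrow(cohort)), function(i) {
    k <- cohort[[num]][i]; m <- cohort[[den]][i]
    c(rep(1, k), rep(0, m - k))
  }), use.names = FALSE)
  out
}

# model-driven simulation used by recovery/selection experiments
model_cohort <- function(n, seed, n_noise = 0L) {
  sample_cohort(cohort_config(n, seed = seed, stage_mode = "MODEL_DRIVEN",
                              n_noise = n_noise))$cohort
}
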