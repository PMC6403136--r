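test_that("intercept-only aggregated fit recovers the closed-form pooled MLE", {
  ch <- toy_cohort()
  fit <- fit_stage_logistic(ch, "EUPLOID_PER_MII", predictors = character(0))
  expect_equal(unname(fit$coefficients),
               qlogis(sum(ch$n_euploid) / sum(ch$n_mii)), tolerance = 1e-8)
  expect_gt(fit$aicc, fit$aic)
})

test_that("aggregated binomial likelihood equals the expanded Bernoulli fit", {
  ch <- model_cohort(50, seed = 31)
  ch <- ch[ch$n_mii > 0, ]
  agg <- fit_stage_logistic(ch, "EUPLOID_PER_MII")
  ex <- expand_bernoulli(ch, "n_euploid", "n_mii")
  grp <- ifelse(ex$sperm_source == "testicle" &
                  ex$azoospermia_type == "non_obstructive", 0, 1)
  ac <- ex$female_age - 38.9066
  bern <- glm(ex$outcome ~ grp + I(grp * ac) + I((1 - grp) * ac),
              family = binomial(),
              control = glm.control(epsilon = 1e-12, maxit = 200))
  expect_equal(unname(agg$coefficients), unname(coef(bern)), tolerance = 1e-8)
  expect_equal(agg$loglik, as.numeric(logLik(bern)) +
                 sum(lchoose(ch$n_mii, ch$n_euploid)), tolerance = 1e-6)
})

test_that("stage fits recover generating coefficients and flag degeneracies", {
  ch <- model_cohort(5000, seed = 37)
  fit <- suppressWarnings(fit_stage_logistic(ch, "EUPLOID_PER_MII"))
  truth <- c(PUB$a, PUB$b, PUB$c, PUB$d)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
  # exported coefficients reproduce the fit's probabilities with covariance CI
  cf <- as_coefficients(fit)
  est <- euploid_prob_per_mii(35, "EJACULATE_LIKE", cf)
  expect_true(est$ci_low < est$p && est$p < est$ci_high)
  expect_false(is.null(cf$covariance))

  sep <- toy_cohort(n = 20)
  sep$split <- as.numeric(seq_len(20) <= 10)
  sep$n_euploid <- ifelse(sep$split == 1, sep$n_mii, 0L)
  sep$n_blast <- pmax(sep$n_blast, sep$n_euploid)
  sep$n_2pn <- pmax(sep$n_2pn, sep$n_blast)
  suppressWarnings(
    expect_error(fit_stage_logistic(sep, "EUPLOID_PER_MII",
                                    predictors = "split"),
                 "separation"))

  chz <- toy_cohort()
  chz$n_2pn[1:3] <- 0L; chz$n_blast[1:3] <- 0L; chz$n_euploid[1:3] <- 0L
  expect_warning(fit_stage_logistic(chz, "BLAST_PER_2PN",
                                    predictors = character(0)),
                 "zero-denominator")
})

test_that("negative-binomial fit estimates dispersion and detects the Poisson boundary", {
  set.seed(41)
  y_pois <- rpois(3000, 0.8)
  expect_warning(fitp <- fit_negative_binomial(count_cohort(y_pois)),
                 "Poisson boundary")
  expect_lt(fitp$dispersion, 0.05)
  ll_pois <- as.numeric(logLik(glm(y_pois ~ 1, family = poisson())))
  expect_lt(abs(fitp$loglik - ll_pois), 0.5)

  y_nb <- rnbinom(3000, size = 2 / 3, mu = 0.74)  # dispersion 1.5
  expect_gt(var(y_nb), mean(y_nb))
  fitnb <- fit_negative_binomial(count_cohort(y_nb))
  expect_equal(unname(fitnb$coefficients[1]), log(0.74), tolerance = 0.15)
  expect_equal(fitnb$dispersion, 1.5, tolerance = 0.25)
})

test_that("negative-binomial interval estimates cover the generating parameters", {
  n_rep <- 50
  cover_mu <- cover_disp <- logical(n_rep)
  set.seed(43)
  seeds <- sample.int(1e6, n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(seeds[i])
    y <- rnbinom(2000, size = 2 / 3, mu = 0.74)
    fit <- fit_negative_binomial(count_cohort(y))
    ci_b0 <- suppressMessages(confint(fit$model))  # profile likelihood
    cover_mu[i] <- ci_b0[1] <= log(0.74) && log(0.74) <= ci_b0[2]
    lt <- log(fit$theta)
    ci_th <- exp(lt + c(-1, 1) * 1.96 * fit$se_log_theta)
    cover_disp[i] <- ci_th[1] <= 2 / 3 && 2 / 3 <= ci_th[2]
  }
  expect_gte(mean(cover_mu), 0.9)
  expect_gte(mean(cover_disp), 0.9)
})

test_that("ROC AUC equals the tie-corrected concordant-pair fraction", {
  expect_identical(roc_auc(1:4, c(0, 0, 1, 1)), 1)
  expect_identical(roc_auc(1:4, c(1, 1, 0, 0)), 0)
  expect_identical(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both outcome classes")
  expect_error(roc_auc(1:3, c(0, 1)), "equal-length")

  pair_count_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(47)
  for (r in 1:5) {
    s <- sample(1:20, 50, replace = TRUE)  # heavy ties
    y <- rbinom(50, 1, plogis((s - 10) / 5))
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), pair_count_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(s, y),
                 as.numeric(suppressMessages(pROC::auc(y, s))),
                 tolerance = 1e-12)
  }
})

test_that("holdout validation reports stable discrimination on both splits", {
  ch <- model_cohort(4000, seed = 53)
  val <- suppressWarnings(holdout_validate(ch, seed = 59))
  expect_equal(val$train_fraction, 0.8)
  expect_equal(val$n_train + val$n_validation, nrow(ch))
  expect_true(val$auc_train > 0.5 && val$auc_train < 1)
  expect_true(val$auc_validation > 0.5 && val$auc_validation < 1)
  # same seed reproduces the same split and AUCs
  val2 <- suppressWarnings(holdout_validate(ch, seed = 59))
  expect_identical(val[c("auc_train", "auc_validation")],
                   val2[c("auc_train", "auc_validation")])

  flat <- toy_cohort(n = 40)
  flat$n_euploid <- 0L
  expect_error(suppressWarnings(holdout_validate(flat, seed = 1)),
               "degenerate split")
  expect_error(holdout_validate(model_cohort(100, seed = 1)), "seed")
})

test_that("age importance is null without age effects and strong under the shipped model", {
  diffs <- vapply(1:5, function(s) {
    ch <- sample_cohort(cohort_config(400, seed = 60 + s))$cohort
    suppressWarnings(age_importance(ch))$loglik_diff
  }, numeric(1))
  expect_lt(median(diffs), 2)  # constant rates: no age signal
  for (s in 1:3) {
    ch <- model_cohort(347, seed = 70 + s)
    ai <- suppressWarnings(age_importance(ch))
    expect_identical(ai$df, 2L)
    expect_gt(ai$loglik_diff, 5)
    expect_lt(ai$p_value, 1e-3)
  }
})

test_that("yearly effect sizes telescope and approach the small-p limit", {
  cf <- pub_coefs()
  red <- yearly_reduction(cf, "EJACULATE_LIKE")
  expect_equal(red$overall_reduction_pct, 14.4186365769614, tolerance = 1e-9)
  expect_equal(yearly_reduction(cf, "TESTICULAR_NOA")$overall_reduction_pct,
               12.136200842939, tolerance = 1e-9)
  # telescoping identity
  expect_equal(red$geometric_mean,
               (red$p[length(red$p)] / red$p[1])^(1 / (length(red$p) - 1)),
               tolerance = 1e-10)
  # zero slopes: constant p, no reduction
  flat <- art_coefficients(PUB$a, PUB$b, 0, 0, PUB$A0)
  red0 <- yearly_reduction(flat, "EJACULATE_LIKE")
  expect_equal(red0$overall_reduction_pct, 0, tolerance = 1e-12)
  expect_true(all(abs(red0$ratios - 1) < 1e-12))
  # small-p limit: the year ratio converges to exp(c)
  red80 <- yearly_reduction(cf, "EJACULATE_LIKE", 80, 82, validate = FALSE)
  expect_equal(red80$ratios[1], exp(PUB$c), tolerance = 1e-3)
  expect_error(yearly_reduction(cf, "EJACULATE_LIKE", 30.5, 40), "integer")
  expect_error(yearly_reduction(cf, "EJACULATE_LIKE", 40, 30), "age_start")
})
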