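test_that("every raw sperm category maps to exactly one coefficient group", {
  cases <- list(
    list(src = "testicle", az = "non_obstructive", dfi = FALSE,
         grp = "TESTICULAR_NOA"),
    list(src = "testicle", az = "obstructive", dfi = FALSE,
         grp = "EJACULATE_LIKE"),
    list(src = "testicle", az = "none", dfi = TRUE, grp = "EJACULATE_LIKE"),
    list(src = "ejaculate", az = NULL, dfi = FALSE, grp = "EJACULATE_LIKE"),
    list(src = "ejaculate", az = NULL, dfi = TRUE, grp = "EJACULATE_LIKE"),
    list(src = "epididymis", az = NULL, dfi = FALSE, grp = "EJACULATE_LIKE")
  )
  for (cs in cases) {
    sp <- sperm_input(cs$src, azoospermia = cs$az, high_dfi = cs$dfi)
    expect_identical(classify_sperm_source(sp), cs$grp,
                     label = paste(cs$src, if (is.null(cs$az)) "-" else cs$az,
                                   cs$dfi))
  }
  expect_error(sperm_input("testicle"), "azoospermia type required")
})

test_that("linear predictor follows the literal published coding", {
  cf <- pub_coefs()
  # expected values from direct arithmetic on the printed constants
  expect_equal(linear_predictor(38.9066, "EJACULATE_LIKE", cf),
               -2.6518 + 0.2231659, tolerance = 1e-12)
  expect_equal(linear_predictor(38.9066, "TESTICULAR_NOA", cf),
               -2.6518, tolerance = 1e-12)
  expect_equal(linear_predictor(24, "EJACULATE_LIKE", cf),
               -2.6518 + 0.2231659 + (-0.2045457) * (24 - 38.9066),
               tolerance = 1e-12)
  expect_equal(linear_predictor(30, "TESTICULAR_NOA", cf),
               -2.6518 + (-0.1530924) * (30 - 38.9066), tolerance = 1e-12)
})

test_that("age limits are enforced: hard 18-50, soft 24-45", {
  cf <- pub_coefs()
  expect_error(linear_predictor(17, "EJACULATE_LIKE", cf), "18-50")
  expect_error(linear_predictor(51, "EJACULATE_LIKE", cf), "18-50")
  expect_warning(linear_predictor(22, "EJACULATE_LIKE", cf), "extrapolat")
  expect_warning(linear_predictor(47, "TESTICULAR_NOA", cf), "extrapolat")
  expect_silent(linear_predictor(24, "TESTICULAR_NOA", cf))
  # unvalidated evaluation permitted for diagnostics
  expect_silent(linear_predictor(80, "EJACULATE_LIKE", cf, validate = FALSE))
})

test_that("probability estimates are the inverse logit of Y with ordered CI", {
  cf <- pub_coefs()
  for (age in c(24, 31.5, 38.9066, 45)) {
    for (grp in c("EJACULATE_LIKE", "TESTICULAR_NOA")) {
      est <- euploid_prob_per_mii(age, grp, cf)
      expect_equal(est$p, plogis(est$y), tolerance = 1e-15)
      expect_true(est$ci_low <= est$p && est$p <= est$ci_high)
      expect_true(est$ci_low >= 0 && est$ci_high <= 1)
    }
  }
  # frozen spot values (inverse logit of the printed equation)
  expect_equal(euploid_prob_per_mii(38.9066, "EJACULATE_LIKE", cf)$p,
               0.0810151025511619, tolerance = 1e-12)
  expect_equal(euploid_prob_per_mii(38.9066, "TESTICULAR_NOA", cf)$p,
               0.0658781540953663, tolerance = 1e-12)
  expect_equal(euploid_prob_per_mii(24, "EJACULATE_LIKE", cf)$p,
               0.650320166627173, tolerance = 1e-12)
})

test_that("zero standard errors collapse the confidence interval onto p", {
  cf <- pub_coefs(se = c(a = 0, b = 0, c = 0, d = 0))
  est <- euploid_prob_per_mii(30, "EJACULATE_LIKE", cf)
  expect_identical(est$ci_low, est$p)
  expect_identical(est$ci_high, est$p)
})

test_that("full covariance is used when attached and matches a manual delta method", {
  se <- PUB$se
  S <- diag(se^2)
  S[1, 2] <- S[2, 1] <- -0.9 * se[1] * se[2]  # strong a-b anticorrelation
  cf <- pub_coefs(covariance = S)
  age <- 33
  est <- euploid_prob_per_mii(age, "EJACULATE_LIKE", cf)
  g <- c(1, 1, age - PUB$A0, 0)
  expect_equal(est$se_y, sqrt(drop(t(g) %*% S %*% g)), tolerance = 1e-12)
  # anticorrelation must narrow the interval relative to independence
  est_diag <- euploid_prob_per_mii(age, "EJACULATE_LIKE", cf,
                                   use_covariance = FALSE)
  expect_lt(est$se_y, est_diag$se_y)
  expect_error(
    euploid_prob_per_mii(age, "EJACULATE_LIKE", pub_coefs(),
                         use_covariance = TRUE),
    "covariance")
})

test_that("p decreases with age in both groups and the sperm-source gap closes with age", {
  cf <- pub_coefs()
  ages <- 24:45
  p_ej <- euploid_prob_per_mii(ages, "EJACULATE_LIKE", cf)$p
  p_noa <- euploid_prob_per_mii(ages, "TESTICULAR_NOA", cf)$p
  expect_true(all(diff(p_ej) < 0))
  expect_true(all(diff(p_noa) < 0))
  # the NOA disadvantage holds up to the crossing of the two linear
  # predictors near age 43, where the age effect has absorbed it
  expect_true(all(p_ej[ages <= 43] > p_noa[ages <= 43]))
  gap_y <- abs(linear_predictor(38:43, "EJACULATE_LIKE", cf) -
                 linear_predictor(38:43, "TESTICULAR_NOA", cf))
  expect_true(all(diff(gap_y) < 0))
})

test_that("coefficient files round-trip and invalid covariances are rejected", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  S <- diag(PUB$se^2)
  cf <- pub_coefs(covariance = S)
  write_coefficients(cf, path)
  cf2 <- read_coefficients(path)
  expect_equal(cf2$a, cf$a)
  expect_equal(cf2$se, cf$se)
  expect_equal(cf2$covariance, cf$covariance, ignore_attr = TRUE)
  expect_equal(linear_predictor(30, "EJACULATE_LIKE", cf2),
               linear_predictor(30, "EJACULATE_LIKE", cf))

  bad <- diag(PUB$se^2); bad[1, 2] <- 0.5  # asymmetric
  expect_error(pub_coefs(covariance = bad), "symmetric")
  neg <- diag(PUB$se^2); neg[1, 2] <- neg[2, 1] <- 1  # not PSD
  expect_error(pub_coefs(covariance = neg), "semi-definite")
  expect_error(art_coefficients(PUB$a, PUB$b, PUB$c, PUB$d, PUB$A0,
                                se = c(a = -1, b = 0, c = 0, d = 0)),
               "non-negative")
})

test_that("the shipped fixture equals the published coefficient set", {
  cf <- default_coefficients()
  expect_equal(cf$a, PUB$a)
  expect_equal(cf$b, PUB$b)
  expect_equal(cf$c, PUB$c)
  expect_equal(cf$d, PUB$d)
  expect_equal(cf$A0, PUB$A0)
  expect_equal(cf$se, PUB$se)
  expect_true(cf$c < 0 && cf$d < 0)
})
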