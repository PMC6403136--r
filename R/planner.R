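#' Minimum number of mature oocytes for a target success probability
#'
#' Inverts the independent-trials success model `1 - (1 - p)^n >= pi` for the
#' smallest positive integer `n`, i.e. the smallest `n` with
#' `n >= log(1 - pi) / log(1 - p)`. Exact integer quotients are kept (a
#' per-oocyte probability of 0.5 and a target of 0.75 gives n = 2, not 3);
#' boundary comparisons use a relative tolerance of 1e-12 so analytic
#' boundaries are not missed to floating point.
#'
#' @param p per-MII-oocyte euploidy probability in (0, 1]; `p >= 1` returns 1.
#' @param pi target probability of obtaining at least one euploid blastocyst,
#'   in (0, 1). Its complement `1 - pi` is the accepted risk.
#' @param cap maximum reportable oocyte number; requirements beyond it are
#'   capped with an "unrealistic target" warning.
#' @return Integer oocyte count.
#' @export
min_mii_for_success <- function(p, pi, cap = 999L) {
  check_pi(pi)
  if (!is.numeric(p) || length(p) != 1L || is.na(p)) {
    abort_input("p must be a single probability")
  }
  if (p <= 0) abort_input("success unattainable: per-oocyte probability is zero")
  if (p >= 1) return(1L)
  tol <- 1e-12
  n <- ceiling(log1p(-pi) / log1p(-p))
  n <- max(n, 1)
  # guard both sides of the analytic boundary
  while (n > 1 && success_prob_with_n(p, n - 1) >= pi * (1 - tol)) n <- n - 1
  while (success_prob_with_n(p, n) < pi * (1 - tol)) n <- n + 1
  if (n > cap) {
    warning(sprintf(
      "required oocyte number %d exceeds %d: unrealistic target, capped", n, cap),
      call. = FALSE)
    n <- cap
  }
  as.integer(n)
}

#' Probability of at least one euploid blastocyst from n mature oocytes
#'
#' Returns `1 - (1 - p)^n` under the assumption that oocytes are independent
#' with a common per-oocyte euploidy probability.
#'
#' @param p per-oocyte probability in \[0, 1\].
#' @param n non-negative integer count of mature oocytes (vectorised).
#' @return Numeric vector of success probabilities.
#' @export
success_prob_with_n <- function(p, n) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort_input("p must be a probability in [0,1]")
  }
  if (!is.numeric(n) || anyNA(n) || any(n < 0) ||
      any(abs(n - round(n)) > 1e-8)) {
    abort_input("n must be a non-negative integer")
  }
  -expm1(round(n) * log1p(-p))
}

check_pi <- function(pi) {
  if (!is.numeric(pi) || length(pi) != 1L || is.na(pi) || pi <= 0 || pi >= 1) {
    abort_input("pi must be in (0,1)")
  }
  invisible(pi)
}

#' Pretreatment plan: minimum oocyte number with confidence limits
#'
#' Maps a per-oocyte probability estimate and its confidence interval into the
#' minimum mature-oocyte number for a chosen success probability. Because the
#' map `p -> n` is monotone decreasing, the interval endpoints swap: the lower
#' oocyte bound comes from the upper probability limit and vice versa. The
#' propagation is valid because the underlying estimators are maximum
#' likelihood and the mappings are monotone.
#'
#' @param estimate an [euploid_prob_per_mii()] result (length 1).
#' @param pi target success probability in (0, 1).
#' @param cap passed to [min_mii_for_success()].
#' @return An object of class `art_plan` with integer `n_min`, `n_ci_low`,
#'   `n_ci_high` (`Inf` with a warning when the lower probability limit
#'   touches zero), `pi`, `risk` and the estimate used.
#' @export
plan_with_ci <- function(estimate, pi, cap = 999L) {
  stopifnot(inherits(estimate, "art_prob"), length(estimate$p) == 1L)
  check_pi(pi)
  n_min <- min_mii_for_success(estimate$p, pi, cap = cap)
  n_lo <- min_mii_for_success(estimate$ci_high, pi, cap = cap)
  if (estimate$ci_low <= 0) {
    warning("lower probability limit is zero: upper oocyte bound unbounded",
            call. = FALSE)
    n_hi <- Inf
  } else {
    n_hi <- min_mii_for_success(estimate$ci_low, pi, cap = cap)
  }
  structure(
    list(n_min = n_min, n_ci_low = n_lo, n_ci_high = n_hi,
         pi = pi, risk = 1 - pi, p_used = estimate),
    class = "art_plan"
  )
}

#' Posttreatment revision: success probability for an observed oocyte count
#'
#' Given the per-oocyte probability estimate and the number of mature oocytes
#' actually collected (or accumulated over retrieval cycles), returns the
#' revised probability of at least one euploid blastocyst with confidence
#' limits mapped from the probability interval (monotone increasing in `p`,
#' so endpoint order is preserved).
#'
#' @param estimate an [euploid_prob_per_mii()] result (length 1).
#' @param n_obs observed mature-oocyte count (non-negative integer).
#' @return An object of class `art_revision` with `n_obs`, `prob`,
#'   `prob_ci_low`, `prob_ci_high`.
#' @export
revise_with_ci <- function(estimate, n_obs) {
  stopifnot(inherits(estimate, "art_prob"), length(estimate$p) == 1L)
  if (!is.numeric(n_obs) || length(n_obs) != 1L || is.na(n_obs) ||
      n_obs < 0 || abs(n_obs - round(n_obs)) > 1e-8) {
    abort_input("n_obs must be a single non-negative integer")
  }
  n_obs <- as.integer(round(n_obs))
  structure(
    list(n_obs = n_obs,
         prob = success_prob_with_n(estimate$p, n_obs),
         prob_ci_low = success_prob_with_n(estimate$ci_low, n_obs),
         prob_ci_high = success_prob_with_n(estimate$ci_high, n_obs),
         p_used = estimate),
    class = "art_revision"
  )
}

#' Success-probability curves over oocyte number
#'
#' Tabulates the probability of at least one euploid blastocyst against the
#' number of mature oocytes (1..`n_max`) for a set of female ages within one
#' sperm group: the numeric content of the published probability-versus-
#' oocyte-number panels.
#'
#' @param coefs an [art_coefficients()] object.
#' @param group `"EJACULATE_LIKE"` or `"TESTICULAR_NOA"`.
#' @param ages numeric vector of female ages (years).
#' @param n_max largest oocyte number tabulated.
#' @return A data frame with columns `age`, `group`, `n`, `p_mii`, `prob`.
#' @export
probability_curve <- function(coefs = default_coefficients(),
                              group = "EJACULATE_LIKE", ages, n_max = 30L) {
  group <- resolve_group(group)
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1) {
    abort_input("n_max must be a positive integer")
  }
  n_max <- as.integer(n_max)
  est <- euploid_prob_per_mii(ages, group, coefs)
  out <- do.call(rbind, lapply(seq_along(ages), function(i) {
    data.frame(age = ages[i], group = group, n = seq_len(n_max),
               p_mii = est$p[i],
               prob = success_prob_with_n(est$p[i], seq_len(n_max)))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.art_plan <- function(x, ...) {
  ci_hi <- if (is.finite(x$n_ci_high)) sprintf("%d", as.integer(x$n_ci_high)) else "unbounded"
  cat(sprintf(
    "Minimum MII oocytes for >=1 euploid blastocyst at %.0f%% success (risk %.0f%%):\n",
    100 * x$pi, 100 * x$risk))
  cat(sprintf("  n = %d (95%% CI %d-%s)\n", x$n_min, x$n_ci_low, ci_hi))
  cat(sprintf("  per-oocyte euploidy probability p = %.4f (CI %.4f-%.4f)\n",
              x$p_used$p, x$p_used$ci_low, x$p_used$ci_high))
  invisible(x)
}

#' @export
print.art_revision <- function(x, ...) {
  cat(sprintf(
    "Probability of >=1 euploid blastocyst with %d MII oocyte%s:\n",
    x$n_obs, if (x$n_obs == 1) "" else "s"))
  cat(sprintf("  %.4f (95%% CI %.4f-%.4f)\n",
              x$prob, x$prob_ci_low, x$prob_ci_high))
  invisible(x)
}
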