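#' Describe the sperm used for ICSI
#'
#' Raw sperm description as entered at the point of care. When the source is
#' testicular the type of azoospermia must be stated explicitly (including
#' `"none"` for non-azoospermic men with high DNA fragmentation who have
#' testicular sperm retrieved), because only testicular sperm from
#' non-obstructive azoospermia carries a distinct model coefficient.
#'
#' @param source `"ejaculate"`, `"epididymis"` or `"testicle"`.
#' @param azoospermia `"none"`, `"obstructive"` or `"non_obstructive"`.
#'   Required when `source = "testicle"`; ignored otherwise.
#' @param high_dfi logical; high sperm DNA fragmentation index. Carried as
#'   metadata only: it does not alter the model group.
#'
#' @return An object of class `art_sperm`.
#' @export
sperm_input <- function(source = c("ejaculate", "epididymis", "testicle"),
                        azoospermia = NULL, high_dfi = FALSE) {
  source <- match.arg(source)
  if (source == "testicle" && is.null(azoospermia)) {
    abort_input("azoospermia type required when sperm source is testicular")
  }
  if (is.null(azoospermia)) azoospermia <- "none"
  azoospermia <- match.arg(azoospermia, c("none", "obstructive", "non_obstructive"))
  stopifnot(is.logical(high_dfi), length(high_dfi) == 1L, !is.na(high_dfi))
  structure(list(source = source, azoospermia = azoospermia,
                 high_dfi = high_dfi),
            class = "art_sperm")
}

#' Map a raw sperm description to its model coefficient group
#'
#' The model distinguishes exactly two groups: testicular sperm from men with
#' non-obstructive azoospermia (`"TESTICULAR_NOA"`), and everything else
#' (`"EJACULATE_LIKE"`): ejaculated sperm, epididymal sperm, testicular sperm
#' from obstructive azoospermia, and testicular sperm from non-azoospermic men
#' with high DNA fragmentation. None of the latter showed an adverse effect on
#' blastocyst euploidy per mature oocyte, so they share the ejaculate
#' coefficients.
#'
#' @param sperm an [sperm_input()] object.
#' @return `"EJACULATE_LIKE"` or `"TESTICULAR_NOA"`.
#' @export
classify_sperm_source <- function(sperm) {
  stopifnot(inherits(sperm, "art_sperm"))
  if (sperm$source == "testicle" && sperm$azoospermia == "non_obstructive") {
    "TESTICULAR_NOA"
  } else {
    "EJACULATE_LIKE"
  }
}

.sperm_groups <- c("EJACULATE_LIKE", "TESTICULAR_NOA")

# vectorised variant used on cohort tables
classify_group_vec <- function(source, azoospermia) {
  ifelse(source == "testicle" & azoospermia == "non_obstructive",
         "TESTICULAR_NOA", "EJACULATE_LIKE")
}

# resolve a sperm description or group label to a group label
resolve_group <- function(sperm) {
  if (inherits(sperm, "art_sperm")) return(classify_sperm_source(sperm))
  if (is.character(sperm) && length(sperm) == 1L && sperm %in% .sperm_groups) {
    return(sperm)
  }
  abort_input("sperm must be an sperm_input() object or one of ",
              paste(.sperm_groups, collapse = ", "))
}

check_age <- function(age, validate = TRUE) {
  if (!is.numeric(age) || anyNA(age) || !all(is.finite(age)) || any(age <= 0)) {
    abort_input("female age must be finite and positive")
  }
  if (!validate) return(invisible(age))
  if (any(age < 18 | age > 50)) {
    abort_input("female age outside the supported range 18-50 years")
  }
  if (any(age < 24 | age > 45)) {
    warning("female age outside 24-45 years: extrapolating beyond the range ",
            "over which the model was characterised", call. = FALSE)
  }
  invisible(age)
}

#' Linear predictor of the euploidy model
#'
#' Evaluates the logit-scale linear predictor `Y` for a female age and sperm
#' group under the literal published coding: the ejaculate-like group gets
#' `a + b + c*(age - A0)`; the testicular-NOA group gets `a + d*(age - A0)`.
#'
#' Ages outside 18--50 years are rejected; ages outside 24--45 years trigger
#' an extrapolation warning.
#'
#' @param age female age in years (vectorised).
#' @param sperm an [sperm_input()] object or a group label
#'   (`"EJACULATE_LIKE"` / `"TESTICULAR_NOA"`).
#' @param coefs an [art_coefficients()] object; defaults to the shipped
#'   published model.
#' @param validate logical; set `FALSE` to evaluate outside the clinical age
#'   limits (used for asymptotic effect-size diagnostics).
#' @return Numeric vector of logit values.
#' @export
linear_predictor <- function(age, sperm, coefs = default_coefficients(),
                             validate = TRUE) {
  stopifnot(inherits(coefs, "art_coefs"))
  group <- resolve_group(sperm)
  check_age(age, validate = validate)
  ac <- age - coefs$A0
  if (group == "EJACULATE_LIKE") {
    coefs$a + coefs$b + coefs$c * ac
  } else {
    coefs$a + coefs$d * ac
  }
}

# delta-method standard error of Y; gradient wrt (a, b, c, d)
se_linear_predictor <- function(age, group, coefs, use_covariance) {
  ac <- age - coefs$A0
  ej <- as.numeric(group == "EJACULATE_LIKE")
  if (use_covariance) {
    S <- coefs$covariance
    vapply(ac, function(z) {
      g <- c(1, ej, ej * z, (1 - ej) * z)
      sqrt(max(drop(t(g) %*% S %*% g), 0))
    }, numeric(1))
  } else {
    se <- coefs$se
    sqrt(se["a"]^2 + ej * se["b"]^2 + (ej * ac)^2 * se["c"]^2 +
           ((1 - ej) * ac)^2 * se["d"]^2)
  }
}

#' Per-MII-oocyte euploidy probability with confidence limits
#'
#' Computes `p = 1/(1 + exp(-Y))`, the probability that a single mature
#' (metaphase-II) oocyte yields a euploid blastocyst, together with a
#' `1 - alpha` Wald confidence interval obtained on the logit scale
#' (`Y +/- z * SE(Y)`) and mapped through the inverse logit; the monotone
#' mapping guarantees the interval stays ordered and inside (0, 1).
#'
#' `SE(Y)` uses the full coefficient covariance when the `art_coefs` object
#' carries one (models fitted in-package do); otherwise the independence
#' (diagonal-SE) approximation is used, which is all the published per-term
#' standard errors support.
#'
#' @inheritParams linear_predictor
#' @param alpha confidence-level complement (default 0.05 for 95% limits).
#' @param use_covariance force (`TRUE`) or suppress (`FALSE`) use of the full
#'   covariance; default uses it when available.
#' @return An object of class `art_prob` with fields `p`, `y`, `se_y`,
#'   `ci_low`, `ci_high`, `alpha`, `age`, `group`.
#' @export
euploid_prob_per_mii <- function(age, sperm, coefs = default_coefficients(),
                                 alpha = 0.05, use_covariance = NULL,
                                 validate = TRUE) {
  stopifnot(inherits(coefs, "art_coefs"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort_input("alpha must be in (0,1)")
  }
  group <- resolve_group(sperm)
  y <- linear_predictor(age, group, coefs, validate = validate)
  if (is.null(use_covariance)) use_covariance <- !is.null(coefs$covariance)
  if (use_covariance && is.null(coefs$covariance)) {
    abort_input("no covariance matrix attached to the coefficients")
  }
  se_y <- unname(se_linear_predictor(age, group, coefs, use_covariance))
  z <- stats::qnorm(1 - alpha / 2)
  structure(
    list(p = stats::plogis(y), y = y, se_y = se_y,
         ci_low = stats::plogis(y - z * se_y),
         ci_high = stats::plogis(y + z * se_y),
         alpha = alpha, age = age, group = group),
    class = "art_prob"
  )
}

#' @export
print.art_prob <- function(x, ...) {
  cat(sprintf("Euploid blastocyst probability per MII oocyte (%s)\n", x$group))
  for (i in seq_along(x$p)) {
    cat(sprintf("  age %5.1f: p = %.4f (%d%% CI %.4f-%.4f)\n",
                x$age[i], x$p[i], round(100 * (1 - x$alpha)),
                x$ci_low[i], x$ci_high[i]))
  }
  invisible(x)
}
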