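#' Model coefficients for the per-MII-oocyte euploidy probability
#'
#' Container for the four coefficients of the logistic model
#' \deqn{Y = a + b\,[\mathrm{ejaculate}] + c\,[\mathrm{ejaculate}](\mathrm{age}-A_0)
#'        + d\,[\mathrm{NOA}](\mathrm{age}-A_0),\qquad p = 1/(1+e^{-Y}),}
#' where the intercept `a` is the testicular-NOA group at the centering age
#' `A0`, `b` is the offset for the ejaculate-like group, and `c`, `d` are the
#' group-specific age slopes (logit per year). Standard errors are carried for
#' delta-method confidence limits on the linear predictor; a full 4x4
#' coefficient covariance matrix (order `a, b, c, d`) may be attached for
#' models fitted in-package, in which case it is preferred over the
#' independence (diagonal-SE) approximation.
#'
#' @param a intercept on the logit scale (testicular-NOA group at `A0`).
#' @param b ejaculate-like group offset (logit scale).
#' @param c age slope for the ejaculate-like group (logit/year); negative for
#'   the shipped model.
#' @param d age slope for the testicular-NOA group (logit/year); negative for
#'   the shipped model.
#' @param A0 centering age in years.
#' @param se named numeric vector with elements `a`, `b`, `c`, `d`: standard
#'   errors on the logit scale; all must be non-negative.
#' @param covariance optional 4x4 symmetric positive semi-definite covariance
#'   matrix of `(a, b, c, d)`; its diagonal must match `se^2`.
#' @param source free-text provenance note.
#' @param alpha default confidence-level complement carried with the
#'   coefficients.
#'
#' @return An object of class `art_coefs`.
#' @seealso [default_coefficients()], [read_coefficients()]
#' @export
art_coefficients <- function(a, b, c, d, A0,
                             se = c(a = 0, b = 0, c = 0, d = 0),
                             covariance = NULL, source = NULL, alpha = 0.05) {
  vals <- c(a = a, b = b, c = c, d = d, A0 = A0)
  if (!all(is.finite(vals))) {
    abort_input("all coefficients and the centering age must be finite numbers")
  }
  se <- se[c("a", "b", "c", "d")]
  if (anyNA(se) || any(se < 0)) {
    abort_input("standard errors must be named (a, b, c, d) and non-negative")
  }
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    if (!identical(dim(covariance), c(4L, 4L))) {
      abort_input("covariance must be a 4x4 matrix ordered (a, b, c, d)")
    }
    if (max(abs(covariance - t(covariance))) > 1e-8 * (1 + max(abs(covariance)))) {
      abort_input("covariance matrix must be symmetric")
    }
    ev <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      abort_input("covariance matrix must be positive semi-definite")
    }
    if (max(abs(sqrt(pmax(diag(covariance), 0)) - se)) > 1e-6 * (1 + max(se))) {
      abort_input("covariance diagonal does not match the squared standard errors")
    }
    dimnames(covariance) <- list(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  }
  structure(
    list(a = a, b = b, c = c, d = d, A0 = A0, se = se,
         covariance = covariance, source = source, alpha = alpha),
    class = "art_coefs"
  )
}

#' Shipped published-model coefficients
#'
#' Reads the packaged coefficient file holding the published nominal logistic
#' fit (logit link) of blastocyst euploidy per mature oocyte: intercept
#' -2.6518, ejaculate offset 0.2231659, age slopes -0.2045457 (ejaculate) and
#' -0.1530924 (testicular-NOA), centering age 38.9066.
#'
#' @return An `art_coefs` object.
#' @export
default_coefficients <- function() {
  read_coefficients(system.file("extdata", "table2.json", package = "artcalc",
                                mustWork = TRUE))
}

#' Read / write coefficient files
#'
#' Coefficient files are JSON objects with fields `a`, `b`, `c`, `d`, `A0`,
#' `se` (object with `a`..`d`), optional `covariance` (4x4, row-major) and
#' `meta` (`source`, `alpha`).
#'
#' @param path file path.
#' @return `read_coefficients()` returns an `art_coefs` object;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) abort_input("coefficient file not found: ", path)
  x <- jsonlite::fromJSON(path)
  need <- c("a", "b", "c", "d", "A0", "se")
  if (!all(need %in% names(x))) {
    abort_input("coefficient file must contain fields: ",
                paste(need, collapse = ", "))
  }
  covar <- NULL
  if (!is.null(x$covariance)) {
    covar <- matrix(as.numeric(unlist(x$covariance)), 4, 4, byrow = TRUE)
  }
  art_coefficients(
    a = x$a, b = x$b, c = x$c, d = x$d, A0 = x$A0,
    se = unlist(x$se)[c("a", "b", "c", "d")],
    covariance = covar,
    source = x$meta$source %||% NULL,
    alpha = x$meta$alpha %||% 0.05
  )
}

#' @rdname read_coefficients
#' @param coefs an `art_coefs` object.
#' @export
write_coefficients <- function(coefs, path) {
  stopifnot(inherits(coefs, "art_coefs"))
  out <- list(
    a = coefs$a, b = coefs$b, c = coefs$c, d = coefs$d, A0 = coefs$A0,
    se = as.list(coefs$se),
    meta = list(source = coefs$source %||% "artcalc export",
                alpha = coefs$alpha)
  )
  if (!is.null(coefs$covariance)) {
    out$covariance <- apply(coefs$covariance, 1, as.numeric, simplify = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.art_coefs <- function(x, ...) {
  cat("Per-MII-oocyte euploidy model (logit link)\n")
  cat(sprintf("  Y = a + b[ej] + c[ej](age - %.4f) + d[NOA](age - %.4f)\n",
              x$A0, x$A0))
  est <- c(a = x$a, b = x$b, c = x$c, d = x$d)
  tab <- data.frame(estimate = est, se = x$se)
  print(round(tab, 7))
  if (!is.null(x$covariance)) cat("  (full coefficient covariance attached)\n")
  if (!is.null(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation errors carry a condition class so the command-line wrapper can
# map them to a usage exit code.
abort_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("artcalc_input_error", "error")))
}
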