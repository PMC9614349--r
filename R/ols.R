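#' @keywords internal
new_iht_fit <- function(data, beta, fit_class, h = 0L, cons = NULL,
                        active = integer(0), lagrange = numeric(0)) {
  beta <- drop(beta)
  resid <- data$y - drop(data$X %*% beta)
  rss <- sum(resid^2)
  s2n <- residual_variance(rss, data$n, data$k, h, fit_class, "naive")
  # a saturated fit (no residual degrees of freedom) has no corrected
  # variance; leave it (and the information matrix) undefined
  s2c <- tryCatch(residual_variance(rss, data$n, data$k, h, fit_class,
                                    "corrected"),
                  error = function(e) NA_real_)
  structure(
    list(
      beta = beta,
      residuals = resid,
      fitted = drop(data$X %*% beta),
      rss = rss,
      s2_naive = s2n,
      s2_corrected = s2c,
      info_unit = if (is.finite(s2c) && s2c > 0)
        unit_information(data$X, s2c) else NULL,
      fit_class = fit_class,
      h = as.integer(h),
      data = data,
      constraints = cons,
      active = active,
      lagrange = lagrange
    ),
    class = "iht_fit"
  )
}

#' Ordinary least squares fit
#'
#' Unconstrained fit of the linear model `y = X beta + e` by QR-based least
#' squares. The returned object carries every shared quantity the test
#' statistics consume: coefficients, residual sum of squares, the naive
#' (`RSS/n`, the maximum-likelihood estimate) and corrected (`RSS/(n-k)`)
#' residual variances, and the unit information matrix.
#'
#' @param data An `iht_data` object (see [regression_data()]), or a data
#'   frame coerced via [as_regression_data()].
#' @return An object of class `iht_fit` with `fit_class = "unconstrained"`.
#' @examples
#' d <- regression_data(c(1, 2, 3), cbind(1, c(0, 1, 2)))
#' fit_ols(d)$beta
#' @export
fit_ols <- function(data) {
  if (is.data.frame(data)) data <- as_regression_data(data)
  stopifnot(inherits(data, "iht_data"))
  qrx <- qr(data$X)
  if (qrx$rank < data$k) {
    stop("design matrix is rank deficient; cannot fit", call. = FALSE)
  }
  beta <- qr.coef(qrx, data$y)
  new_iht_fit(data, beta, "unconstrained")
}

#' Residual variance estimators
#'
#' The naive estimator is `rss/n` for every fit class (the plug-in
#' maximum-likelihood variance). The degrees-of-freedom corrected estimator
#' divides by `n - k` for unconstrained and inequality-constrained fits and
#' by `n - (k - h)` for equality-constrained fits, `h` being the row rank of
#' the constraint matrix: each equality row removes one free coefficient.
#'
#' @param rss Residual sum of squares (non-negative).
#' @param n Sample size.
#' @param k Number of design-matrix columns.
#' @param h Number of constraint rows (only used for the equality class).
#' @param fit_class `"unconstrained"`, `"inequality"` or `"equality"`.
#' @param version `"naive"` or `"corrected"`.
#' @return The variance estimate, a non-negative scalar.
#' @export
residual_variance <- function(rss, n, k, h = 0,
                              fit_class = c("unconstrained", "inequality", "equality"),
                              version = c("corrected", "naive")) {
  fit_class <- match.arg(fit_class)
  version <- match.arg(version)
  stopifnot(rss >= 0, n >= 1)
  denom <- switch(version,
    naive = n,
    corrected = if (fit_class == "equality") n - (k - h) else n - k
  )
  if (denom <= 0) {
    stop("non-positive degrees of freedom in the variance denominator", call. = FALSE)
  }
  rss / denom
}

#' Unit information matrix
#'
#' `X'X / (n * s2)`: the average Fisher information per observation for the
#' regression coefficients under Gaussian errors with variance `s2`.
#'
#' @param X Design matrix.
#' @param s2 Positive residual-variance estimate.
#' @return A symmetric positive-definite `k x k` matrix.
#' @export
unit_information <- function(X, s2) {
  if (!is.numeric(s2) || length(s2) != 1 || !is.finite(s2) || s2 <= 0) {
    stop("s2 must be a positive scalar", call. = FALSE)
  }
  crossprod(X) / (nrow(X) * s2)
}

#' Coefficient covariance matrix
#'
#' `(1/n) I1^-1`, which simplifies to `s2_corrected * (X'X)^-1`.
#'
#' @param fit An `iht_fit` object.
#' @return A symmetric positive-definite `k x k` matrix.
#' @export
vcov_beta <- function(fit) {
  stopifnot(inherits(fit, "iht_fit"))
  solve(fit$info_unit) / fit$data$n
}

#' Gaussian log-likelihood with a plug-in scalar variance
#'
#' `-(n/2) log(2 pi s2) - RSS(beta) / (2 s2)`. The variance is not profiled:
#' each test statistic dictates which residual-variance estimate is plugged
#' in.
#'
#' @param data An `iht_data` object.
#' @param beta Coefficient vector.
#' @param s2 Positive variance.
#' @return The log-likelihood, a scalar.
#' @export
gaussian_loglik <- function(data, beta, s2) {
  stopifnot(inherits(data, "iht_data"))
  if (s2 <= 0) stop("s2 must be positive", call. = FALSE)
  rss <- sum((data$y - drop(data$X %*% beta))^2)
  -(data$n / 2) * log(2 * pi * s2) - rss / (2 * s2)
}

#' Score function of the Gaussian regression log-likelihood
#'
#' The gradient of [gaussian_loglik()] in `beta`: `X'(y - X beta) / s2`.
#'
#' @inheritParams gaussian_loglik
#' @return Numeric vector of length `k`.
#' @export
score_vector <- function(data, beta, s2) {
  stopifnot(inherits(data, "iht_data"))
  if (s2 <= 0) stop("s2 must be positive", call. = FALSE)
  drop(crossprod(data$X, data$y - drop(data$X %*% beta))) / s2
}

#' @export
print.iht_fit <- function(x, ...) {
  cat(sprintf("<iht_fit: %s, n = %d, k = %d>\n",
              x$fit_class, x$data$n, x$data$k))
  cat("  beta:", format(x$beta, digits = 4), "\n")
  cat(sprintf("  rss = %.6g, s2(naive) = %.6g, s2(corrected) = %.6g\n",
              x$rss, x$s2_naive, x$s2_corrected))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a constrained or unconstrained regression fit
#'
#' One row per coefficient. Standard errors are reported only for the
#' unconstrained fit, where the usual covariance formula applies.
#'
#' @param x An `iht_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and (for unconstrained
#'   fits) `std.error`.
#' @export
tidy.iht_fit <- function(x, ...) {
  term <- colnames(x$data$X)
  if (is.null(term)) term <- paste0("beta", seq_along(x$beta) - 1)
  out <- tibble::tibble(term = term, estimate = unname(x$beta))
  if (x$fit_class == "unconstrained") {
    out$std.error <- sqrt(diag(vcov_beta(x)))
  }
  out
}

#' Fit-level summary of a regression fit
#'
#' @param x An `iht_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the fit class, sample size, number of
#'   coefficients, residual sum of squares and both variance estimates.
#' @export
glance.iht_fit <- function(x, ...) {
  tibble::tibble(
    fit_class = x$fit_class,
    n = x$data$n,
    k = x$data$k,
    h = x$h,
    rss = x$rss,
    s2_naive = x$s2_naive,
    s2_corrected = x$s2_corrected,
    logLik = if (is.finite(x$s2_corrected) && x$s2_corrected > 0)
      gaussian_loglik(x$data, x$beta, x$s2_corrected) else NA_real_
  )
}
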