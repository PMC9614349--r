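# Test-statistic catalogue.
#
# Naming: hat = unconstrained fit, tilde = inequality-constrained fit,
# bar = equality-constrained fit. All statistics come in a "naive"
# (variance RSS/n) and a "corrected" (degrees-of-freedom adjusted) version.
# Score functions are evaluated with the plug-in variance of the fit they
# belong to (the same convention the informative LRT uses for its two
# log-likelihoods); the score difference S(tilde) - S(bar) then lies in the
# row space of R', which is what makes the information-, Robertson- and
# VCOV-forms of the score statistic coincide.

#' @keywords internal
s2_of <- function(fit, version) {
  switch(version, naive = fit$s2_naive, corrected = fit$s2_corrected)
}

#' @keywords internal
qform_solve <- function(v, M) {
  v <- drop(v)
  drop(crossprod(v, solve(M, v)))
}

#' @keywords internal
check_same_data <- function(a, b) {
  if (!isTRUE(all.equal(a$data$y, b$data$y)) ||
      !isTRUE(all.equal(a$data$X, b$data$X))) {
    stop("fits were not computed on the same data", call. = FALSE)
  }
}

#' @keywords internal
check_same_constraints <- function(fit_eq, fit_ineq) {
  ce <- fit_eq$constraints
  ci <- fit_ineq$constraints
  if (is.null(ce) || is.null(ci) ||
      !isTRUE(all.equal(ce$R, ci$R)) || !isTRUE(all.equal(ce$rhs, ci$rhs))) {
    stop("the equality and inequality fits use different constraint sets",
         call. = FALSE)
  }
}

#' @keywords internal
new_test_result <- function(statistic, version, value, data, h, q,
                            distribution = NA_character_,
                            pvalue = NA_real_) {
  tibble::tibble(
    statistic = statistic,
    version = version,
    value = value,
    distribution = distribution,
    pvalue = pvalue,
    h = as.integer(h),
    q = as.integer(q),
    n = data$n,
    k = data$k
  )
}

#' Difference of score vectors between the two constrained fits
#'
#' `S(beta_tilde) - S(beta_bar)`, each score evaluated with the plug-in
#' residual variance of its own fit (naive or corrected as requested).
#'
#' @param fit_ineq Inequality-constrained `iht_fit`.
#' @param fit_eq Equality-constrained `iht_fit`.
#' @param version `"naive"` or `"corrected"`.
#' @return Numeric vector of length `k`; lies in the row space of `R'`.
#' @export
score_difference <- function(fit_ineq, fit_eq, version = c("corrected", "naive")) {
  version <- match.arg(version)
  check_same_data(fit_ineq, fit_eq)
  check_same_constraints(fit_eq, fit_ineq)
  data <- fit_ineq$data
  score_vector(data, fit_ineq$beta, s2_of(fit_ineq, version)) -
    score_vector(data, fit_eq$beta, s2_of(fit_eq, version))
}

# ---- classical statistics ---------------------------------------------------

#' Classical Wald statistic
#'
#' `n (R b - rhs)' (R I1^-1 R')^-1 (R b - rhs)` evaluated at the
#' unconstrained estimate, with the unit information built from the naive or
#' corrected variance.
#'
#' @param fit_u Unconstrained `iht_fit`.
#' @param cons An [iht_constraints] object.
#' @param version `"naive"` or `"corrected"`.
#' @return A one-row tibble (see [iht_test()] for the column layout).
#' @export
wald_classical <- function(fit_u, cons, version = c("corrected", "naive")) {
  version <- match.arg(version)
  stopifnot(fit_u$fit_class == "unconstrained")
  data <- fit_u$data
  info <- unit_information(data$X, s2_of(fit_u, version))
  gap <- drop(cons$R %*% fit_u$beta) - cons$rhs
  val <- data$n * qform_solve(gap, cons$R %*% solve(info, t(cons$R)))
  new_test_result("wald", version, val, data, cons$h, cons$q)
}

#' Classical likelihood-ratio statistic
#'
#' `-2 [l(beta_bar) - l(beta_hat)]` with each log-likelihood evaluated at
#' its own plug-in variance. The naive version equals
#' `n log(RSS_bar / RSS_hat)` exactly.
#'
#' @param fit_u Unconstrained `iht_fit`.
#' @param fit_eq Equality-constrained `iht_fit` on the same data.
#' @param version `"naive"` or `"corrected"`.
#' @return A one-row tibble.
#' @export
lrt_classical <- function(fit_u, fit_eq, version = c("corrected", "naive")) {
  version <- match.arg(version)
  stopifnot(fit_u$fit_class == "unconstrained", fit_eq$fit_class == "equality")
  check_same_data(fit_u, fit_eq)
  data <- fit_u$data
  val <- -2 * (gaussian_loglik(data, fit_eq$beta, s2_of(fit_eq, version)) -
               gaussian_loglik(data, fit_u$beta, s2_of(fit_u, version)))
  h <- fit_eq$h
  new_test_result("lrt", version, val, data, h, 0L)
}

#' Classical score statistic
#'
#' `(1/n) S(beta_bar)' Ibar1^-1 S(beta_bar)`, score and information both
#' evaluated at the equality-constrained fit.
#'
#' @param fit_eq Equality-constrained `iht_fit`.
#' @param version `"naive"` or `"corrected"`.
#' @return A one-row tibble.
#' @export
score_classical <- function(fit_eq, version = c("corrected", "naive")) {
  version <- match.arg(version)
  stopifnot(fit_eq$fit_class == "equality")
  data <- fit_eq$data
  s2 <- s2_of(fit_eq, version)
  s <- score_vector(data, fit_eq$beta, s2)
  info <- unit_information(data$X, s2)
  val <- qform_solve(s, info) / data$n
  new_test_result("score", version, val, data, fit_eq$h, 0L)
}

#' Classical F statistic
#'
#' RSS form `(1/h) (RSS_bar - RSS_hat) / S2_hat`, or the equivalent
#' information form `(n/h) (R b - rhs)' (R I1^-1 R')^-1 (R b - rhs)`. Both
#' forms are implemented independently so they can cross-check each other.
#'
#' @param fit_u Unconstrained `iht_fit`.
#' @param fit_eq Equality-constrained `iht_fit` on the same data.
#' @param cons An [iht_constraints] object (needed for the information form).
#' @param version `"naive"` or `"corrected"`.
#' @param form `"rss"` or `"info"`.
#' @return A one-row tibble.
#' @export
f_classical <- function(fit_u, fit_eq, cons, version = c("corrected", "naive"),
                        form = c("rss", "info")) {
  version <- match.arg(version)
  form <- match.arg(form)
  check_same_data(fit_u, fit_eq)
  data <- fit_u$data
  h <- cons$h
  if (h < 1) stop("h must be at least 1", call. = FALSE)
  val <- if (form == "rss") {
    (fit_eq$rss - fit_u$rss) / h / s2_of(fit_u, version)
  } else {
    info <- unit_information(data$X, s2_of(fit_u, version))
    gap <- drop(cons$R %*% fit_u$beta) - cons$rhs
    data$n / h * qform_solve(gap, cons$R %*% solve(info, t(cons$R)))
  }
  new_test_result("f", version, val, data, h, 0L)
}

#' t statistic for a single coefficient
#'
#' `(b - null_value) / SE(b)` with the standard error from the corrected
#' coefficient covariance; `df = n - k`. Two-sided p-values double the upper
#' tail at `|t|`; one-sided p-values allocate the whole level to the side
#' named by `alternative`.
#'
#' @param fit_u Unconstrained `iht_fit`.
#' @param coef_index Index of the coefficient (1-based, intercept is 1).
#' @param null_value Hypothesised value, default 0.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A one-row tibble; `value` is signed.
#' @export
t_statistic <- function(fit_u, coef_index, null_value = 0,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(fit_u$fit_class == "unconstrained")
  data <- fit_u$data
  if (coef_index < 1 || coef_index > data$k) {
    stop("coef_index out of range", call. = FALSE)
  }
  se <- sqrt(diag(vcov_beta(fit_u))[coef_index])
  tval <- (fit_u$beta[coef_index] - null_value) / se
  df <- data$n - data$k
  p <- switch(alternative,
    two.sided = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    greater = stats::pt(tval, df, lower.tail = FALSE),
    less = stats::pt(tval, df)
  )
  new_test_result("t", "corrected", unname(tval), data, 1L, 0L,
                  distribution = paste0("t(", df, ")"), pvalue = unname(p))
}

# ---- informative statistics -------------------------------------------------

#' Informative likelihood-ratio statistic
#'
#' `-2 [l(beta_bar) - l(beta_tilde)]`, comparing the equality-constrained
#' (null) fit to the inequality-constrained (order-restricted) fit. Each
#' log-likelihood is evaluated with its own fit's plug-in variance: the
#' corrected version uses `RSS_bar / (n - (k - h))` and
#' `RSS_tilde / (n - k)`, the naive version uses `RSS/n` in both, in which
#' case the statistic equals `n log(RSS_bar / RSS_tilde)` exactly. The
#' corrected version can be negative in small samples because the two
#' variance denominators differ; the mixture p-value of a non-positive value
#' is 1.
#'
#' @param fit_eq Equality-constrained `iht_fit`.
#' @param fit_ineq Inequality-constrained `iht_fit` on the same data and
#'   constraint rows.
#' @param version `"naive"` or `"corrected"`.
#' @return A one-row tibble.
#' @export
lrt_informative <- function(fit_eq, fit_ineq, version = c("corrected", "naive")) {
  version <- match.arg(version)
  stopifnot(fit_eq$fit_class == "equality")
  check_same_data(fit_eq, fit_ineq)
  check_same_constraints(fit_eq, fit_ineq)
  data <- fit_eq$data
  val <- -2 * (gaussian_loglik(data, fit_eq$beta, s2_of(fit_eq, version)) -
               gaussian_loglik(data, fit_ineq$beta, s2_of(fit_ineq, version)))
  cons <- fit_ineq$constraints
  new_test_result("lrt", version, val, data, cons$h, cons$q)
}

#' Informative Wald statistic
#'
#' Information form `(n / S2_hat) (R b~ - rhs)' (R W^-1 R')^-1 (R b~ - rhs)`
#' with `W = X'X / n`, or the algebraically identical VCOV form
#' `(R b~ - rhs)' (R VCOV(b^) R')^-1 (R b~ - rhs)` (identical for the
#' corrected version, since the coefficient covariance is defined through
#' the corrected variance). The two forms are implemented independently.
#'
#' @param fit_u Unconstrained `iht_fit` (supplies the variance scale).
#' @param fit_ineq Inequality-constrained `iht_fit`.
#' @param cons An [iht_constraints] object.
#' @param version `"naive"` or `"corrected"`.
#' @param form `"info"` or `"vcov"`.
#' @param information `"unconstrained"` (default) scales by the
#'   unconstrained variance; `"inequality"` substitutes the
#'   inequality-fit variance into the information matrix.
#' @return A one-row tibble.
#' @export
wald_informative <- function(fit_u, fit_ineq, cons,
                             version = c("corrected", "naive"),
                             form = c("info", "vcov"),
                             information = c("unconstrained", "inequality")) {
  version <- match.arg(version)
  form <- match.arg(form)
  information <- match.arg(information)
  check_same_data(fit_u, fit_ineq)
  data <- fit_u$data
  gap <- drop(cons$R %*% fit_ineq$beta) - cons$rhs
  name <- if (form == "vcov") "wald_vcov" else "wald_info"
  val <- if (form == "info") {
    s2 <- if (information == "unconstrained") s2_of(fit_u, version) else s2_of(fit_ineq, version)
    W <- crossprod(data$X) / data$n
    data$n / s2 * qform_solve(gap, cons$R %*% solve(W, t(cons$R)))
  } else {
    qform_solve(gap, cons$R %*% vcov_beta(fit_u) %*% t(cons$R))
  }
  new_test_result(name, version, val, data, cons$h, cons$q)
}

#' Distance statistic
#'
#' Differences the squared `W`-metric distances from the unconstrained
#' estimate to the equality set and to the constraint cone
#' (`W = X'X / n`; see [distance_value()]), scaled by `n / S2_hat`. With
#' [distance_value()]'s full-quadratic convention the statistic is
#' `(n / S2_hat) [d(beta_bar) - d(beta_tilde)]` (the familiar leading 2
#' belongs to the half-quadratic convention for `d`), which makes the
#' corrected version exactly identical to the informative Wald statistic.
#'
#' @param fit_u Unconstrained `iht_fit`.
#' @param cons An [iht_constraints] object.
#' @param version `"naive"` or `"corrected"`.
#' @return A one-row tibble.
#' @export
d_statistic <- function(fit_u, cons, version = c("corrected", "naive")) {
  version <- match.arg(version)
  stopifnot(fit_u$fit_class == "unconstrained")
  data <- fit_u$data
  W <- crossprod(data$X) / data$n
  d_eq <- distance_value(fit_u$beta, W, cons, "eq")
  d_in <- distance_value(fit_u$beta, W, cons, "ineq")
  val <- max(0, data$n / s2_of(fit_u, version) * (d_eq - d_in))
  new_test_result("d", version, val, data, cons$h, cons$q)
}

#' F-bar statistic
#'
#' RSS form `(RSS_bar - RSS_tilde) / S2_hat` (no `1/h` factor), or the
#' information form `n (R b~)' (R I1^-1 R')^-1 (R b~)`, equal to the RSS
#' form whenever `rhs = 0`. Both forms are implemented independently.
#'
#' @param fit_eq Equality-constrained `iht_fit`.
#' @param fit_ineq Inequality-constrained `iht_fit`.
#' @param fit_u Unconstrained `iht_fit` (supplies the variance scale).
#' @param version `"naive"` or `"corrected"`.
#' @param form `"rss"` or `"info"`.
#' @param information `"unconstrained"` (default) or `"inequality"`; which
#'   fit's variance builds the information matrix in the `"info"` form.
#' @return A one-row tibble.
#' @export
fbar_statistic <- function(fit_eq, fit_ineq, fit_u,
                           version = c("corrected", "naive"),
                           form = c("rss", "info"),
                           information = c("unconstrained", "inequality")) {
  version <- match.arg(version)
  form <- match.arg(form)
  information <- match.arg(information)
  check_same_data(fit_eq, fit_ineq)
  check_same_data(fit_eq, fit_u)
  check_same_constraints(fit_eq, fit_ineq)
  data <- fit_u$data
  cons <- fit_ineq$constraints
  val <- if (form == "rss") {
    (fit_eq$rss - fit_ineq$rss) / s2_of(fit_u, version)
  } else {
    s2 <- if (information == "unconstrained") s2_of(fit_u, version) else s2_of(fit_ineq, version)
    info <- unit_information(data$X, s2)
    gap <- drop(cons$R %*% fit_ineq$beta) - cons$rhs
    data$n * qform_solve(gap, cons$R %*% solve(info, t(cons$R)))
  }
  new_test_result("fbar", version, val, data, cons$h, cons$q)
}

#' Score statistic, U form
#'
#' `(1/(n S2_hat)) U' (R W^-1 R')^-1 U` with
#' `U = R W^-1 [S(beta_tilde) - S(beta_bar)]` and `W = X'X / n`.
#'
#' @param fit_eq Equality-constrained `iht_fit`.
#' @param fit_ineq Inequality-constrained `iht_fit`.
#' @param fit_u Unconstrained `iht_fit` (supplies the variance scale).
#' @param version `"naive"` or `"corrected"`.
#' @return A one-row tibble.
#' @export
score_u_statistic <- function(fit_eq, fit_ineq, fit_u,
                              version = c("corrected", "naive")) {
  version <- match.arg(version)
  check_same_data(fit_eq, fit_u)
  data <- fit_u$data
  cons <- fit_ineq$constraints
  ds <- score_difference(fit_ineq, fit_eq, version)
  W <- crossprod(data$X) / data$n
  U <- drop(cons$R %*% solve(W, ds))
  val <- qform_solve(U, cons$R %*% solve(W, t(cons$R))) /
    (data$n * s2_of(fit_u, version))
  new_test_result("score_u", version, val, data, cons$h, cons$q)
}

#' Score statistic, null-information form
#'
#' `(1/n) [S(beta_bar) - S(beta_tilde)]' Ibar1^-1 [S(beta_bar) - S(beta_tilde)]`
#' with the information matrix of the equality-constrained (null) fit built
#' from its naive or corrected variance.
#'
#' @inheritParams score_u_statistic
#' @return A one-row tibble.
#' @export
score_nullinfo_statistic <- function(fit_eq, fit_ineq,
                                     version = c("corrected", "naive")) {
  version <- match.arg(version)
  data <- fit_eq$data
  cons <- fit_ineq$constraints
  ds <- score_difference(fit_ineq, fit_eq, version)
  info <- unit_information(data$X, s2_of(fit_eq, version))
  val <- qform_solve(ds, info) / data$n
  new_test_result("score_nullinfo", version, val, data, cons$h, cons$q)
}

#' Score statistic, information form (three equivalent expressions)
#'
#' Information form `(1/n) P' (R I1^-1 R')^-1 P` with
#' `P = R I1^-1 [S(beta_tilde) - S(beta_bar)]`; the Robertson form
#' `(1/n) [S(beta_tilde) - S(beta_bar)]' I1^-1 [S(beta_tilde) - S(beta_bar)]`;
#' and the VCOV form `V' (R VCOV(b^) R')^-1 V` with
#' `V = R VCOV(b^) [S(beta_tilde) - S(beta_bar)]`. Because the score
#' difference lies in the row space of `R'`, the three forms agree (the
#' VCOV form for the corrected version, since the coefficient covariance is
#' defined through the corrected variance). All three are implemented
#' independently.
#'
#' @inheritParams score_u_statistic
#' @param form `"info"`, `"robertson"` or `"vcov"`.
#' @return A one-row tibble.
#' @export
score_info_statistic <- function(fit_eq, fit_ineq, fit_u,
                                 version = c("corrected", "naive"),
                                 form = c("info", "robertson", "vcov")) {
  version <- match.arg(version)
  form <- match.arg(form)
  check_same_data(fit_eq, fit_u)
  data <- fit_u$data
  cons <- fit_ineq$constraints
  ds <- score_difference(fit_ineq, fit_eq, version)
  name <- if (form == "vcov") "score_vcov" else "score_info"
  val <- switch(form,
    info = {
      info <- unit_information(data$X, s2_of(fit_u, version))
      P <- drop(cons$R %*% solve(info, ds))
      qform_solve(P, cons$R %*% solve(info, t(cons$R))) / data$n
    },
    robertson = {
      info <- unit_information(data$X, s2_of(fit_u, version))
      qform_solve(ds, info) / data$n
    },
    vcov = {
      V <- drop(cons$R %*% vcov_beta(fit_u) %*% ds)
      qform_solve(V, cons$R %*% vcov_beta(fit_u) %*% t(cons$R))
    }
  )
  new_test_result(name, version, val, data, cons$h, cons$q)
}
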