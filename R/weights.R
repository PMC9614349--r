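# Chi-bar-squared / F-bar mixture weights (level probabilities).
#
# For z ~ N(0, V) projected onto the cone {x >= 0} in the V^-1 metric,
# w_i is the probability that exactly i components of the projection are
# positive. KKT analysis of the projection gives, for the inactive set B
# and active set A = complement(B):
#   theta_B = z_B - V_BA V_AA^-1 z_A  ~ N(0, V_{BB.A}),
#   lambda_A = V_AA^-1 z_A            ~ N(0, V_AA^-1),
# and the two are independent, so
#   P(inactive set is exactly B) = P(N(0, V_AA^-1) >= 0) * P(N(0, V_BB.A) >= 0).
# Summing over subsets of size i yields w_i (Kudo's decomposition).

#' @keywords internal
is_diag <- function(V, tol = 1e-12) {
  all(abs(V[upper.tri(V)]) < tol * max(diag(V)))
}

#' @keywords internal
orthant_prob <- function(S) {
  d <- NROW(S)
  if (d == 0) return(1)
  if (d == 1) return(0.5)
  C <- stats::cov2cor(S)
  if (d == 2) return(0.25 + asin(C[1, 2]) / (2 * pi))
  if (is_diag(C)) return(0.5^d)
  if (d == 3) {
    return(0.125 + (asin(C[1, 2]) + asin(C[1, 3]) + asin(C[2, 3])) / (4 * pi))
  }
  as.numeric(mvtnorm::pmvnorm(lower = rep(0, d), sigma = C,
                              algorithm = mvtnorm::Miwa(steps = 128)))
}

#' Mixture weights of the chi-bar-squared / F-bar null distribution
#'
#' Computes the level probabilities `w_0, ..., w_q` of the constrained
#' estimator: `w_i` is the probability that the projection of
#' `z ~ N(0, V)` onto the non-negative cone (in the `V^-1` metric)
#' has exactly `i` positive components. The weights sum to one and depend
#' only on the correlation structure of `V` (any scalar factor cancels).
#'
#' Methods: `"closed_form"` handles `q <= 2` and any diagonal kernel (the
#' independent case gives binomial weights); `"mvn_probability"` uses
#' Kudo's subset decomposition with multivariate-normal orthant
#' probabilities (deterministic Miwa quadrature); `"monte_carlo"` counts
#' positive components over repeated cone projections. `"auto"` picks the
#' cheapest exact method and falls back to Monte Carlo for `q > 10`.
#'
#' @param V Symmetric positive-definite `q x q` covariance kernel,
#'   typically [constraint_kernel()].
#' @param method One of `"auto"`, `"closed_form"`, `"mvn_probability"`,
#'   `"monte_carlo"`.
#' @param mc_draws Number of Monte-Carlo draws (used only by
#'   `"monte_carlo"`); a warning is issued below 1e4.
#' @param seed Seed for the Monte-Carlo method (required there, ignored
#'   elsewhere).
#' @return An object of class `chibar_weights`: list with `w` (length
#'   `q + 1`, indices 0..q), `q`, `V`, `method`, and for Monte Carlo
#'   `mc_draws` and `mc_se`.
#' @examples
#' chibar_weights(diag(2))  # (0.25, 0.5, 0.25)
#' @export
chibar_weights <- function(V,
                           method = c("auto", "closed_form", "mvn_probability",
                                      "monte_carlo"),
                           mc_draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (!is.matrix(V)) V <- matrix(V, 1, 1)
  q <- nrow(V)
  if (ncol(V) != q || !isTRUE(all.equal(V, t(V), tolerance = 1e-8))) {
    stop("V must be a symmetric square matrix", call. = FALSE)
  }
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || min(ev) / max(ev) < 1e-12) {
    stop("V must be positive definite", call. = FALSE)
  }
  if (method == "auto") {
    method <- if (q <= 2 || is_diag(stats::cov2cor(V))) "closed_form"
              else if (q <= 10) "mvn_probability"
              else "monte_carlo"
  }
  out <- switch(method,
    closed_form = weights_closed_form(V, q),
    mvn_probability = weights_mvn(V, q),
    monte_carlo = weights_monte_carlo(V, q, mc_draws, seed)
  )
  structure(
    c(list(q = q, V = V, method = method), out),
    class = "chibar_weights"
  )
}

#' @keywords internal
weights_closed_form <- function(V, q) {
  C <- stats::cov2cor(V)
  if (q == 1) {
    w <- c(0.5, 0.5)
  } else if (is_diag(C)) {
    w <- stats::dbinom(0:q, q, 0.5)
  } else if (q == 2) {
    a <- asin(C[1, 2]) / (2 * pi)
    w <- c(0.25 - a, 0.5, 0.25 + a)
  } else {
    stop("no closed form for q > 2 with a non-diagonal kernel; ",
         "use method = \"mvn_probability\" or \"monte_carlo\"", call. = FALSE)
  }
  list(w = w)
}

#' @keywords internal
weights_mvn <- function(V, q) {
  w <- numeric(q + 1)
  idx <- seq_len(q)
  for (m in 0:q) {
    subsets <- utils::combn(q, m, simplify = FALSE)
    for (B in subsets) {
      A <- setdiff(idx, B)
      p_act <- if (length(A) == 0) 1 else
        orthant_prob(solve(V[A, A, drop = FALSE]))
      p_ina <- if (length(B) == 0) 1 else {
        S <- V[B, B, drop = FALSE]
        if (length(A) > 0) {
          S <- S - V[B, A, drop = FALSE] %*%
            solve(V[A, A, drop = FALSE], V[A, B, drop = FALSE])
        }
        orthant_prob(S)
      }
      w[m + 1] <- w[m + 1] + p_act * p_ina
    }
  }
  list(w = w / sum(w))
}

#' @keywords internal
weights_monte_carlo <- function(V, q, mc_draws, seed) {
  if (is.null(seed)) {
    stop("the Monte-Carlo method requires a seed", call. = FALSE)
  }
  mc_draws <- as.integer(mc_draws)
  if (mc_draws < 1e4) {
    warning("fewer than 10^4 Monte-Carlo draws; weights will be imprecise")
  }
  counts <- withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(mc_draws * q), mc_draws, q) %*% chol(V)
    if (is_diag(stats::cov2cor(V))) {
      rowSums(Z > 0)
    } else {
      Vi <- solve(V)
      Aq <- diag(q)
      apply(Z, 1, function(z) {
        sol <- quadprog::solve.QP(Vi, drop(Vi %*% z), Aq, rep(0, q))
        sum(sol$solution > 1e-8 * (1 + max(abs(sol$solution))))
      })
    }
  })
  w <- tabulate(counts + 1L, nbins = q + 1L) / mc_draws
  list(w = w, mc_draws = mc_draws,
       mc_se = sqrt(w * (1 - w) / mc_draws))
}

#' @export
print.chibar_weights <- function(x, ...) {
  cat(sprintf("<chibar_weights: q = %d, method = %s>\n", x$q, x$method))
  lab <- paste0("w", 0:x$q)
  cat(paste(sprintf("%s = %.6f", lab, x$w), collapse = ", "), "\n")
  if (!is.null(x$mc_se)) {
    cat("mc draws:", x$mc_draws,
        " max SE:", format(max(x$mc_se), digits = 3), "\n")
  }
  cat("sum =", format(sum(x$w), digits = 10), "\n")
  invisible(x)
}

#' Covariance kernel of the inequality constraints
#'
#' The weight computation depends only on the cone geometry through
#' `R (X'X)^-1 R'` restricted to the inequality rows; with equality rows
#' present the kernel is the conditional (Schur-complement) covariance of
#' the inequality rows given the equalities. Any scalar variance factor
#' cancels in the weights.
#'
#' @param data An `iht_data` object.
#' @param cons An [iht_constraints] object with at least one inequality row.
#' @return A `q x q` positive-definite matrix.
#' @export
constraint_kernel <- function(data, cons) {
  stopifnot(inherits(data, "iht_data"), inherits(cons, "iht_constraints"))
  if (cons$q == 0) stop("constraint set has no inequality rows", call. = FALSE)
  XtXi <- solve(crossprod(data$X))
  S <- cons$R %*% XtXi %*% t(cons$R)
  ineq <- which(cons$op == ">=")
  eq <- which(cons$op == "=")
  V <- S[ineq, ineq, drop = FALSE]
  if (length(eq) > 0) {
    V <- V - S[ineq, eq, drop = FALSE] %*%
      solve(S[eq, eq, drop = FALSE], S[eq, ineq, drop = FALSE])
  }
  V
}

# ---- mixture tail probabilities --------------------------------------------

#' Chi-bar-squared mixture p-value
#'
#' `sum_i w_i P(chisq(df_offset + i) >= stat)`, where the zero-df component
#' is a point mass at zero (its upper tail is 1 for a non-positive
#' statistic and 0 otherwise). A non-positive statistic therefore has
#' p-value 1.
#'
#' @param stat Observed statistic.
#' @param weights A [chibar_weights] object (or bare weight vector indexed
#'   0..q).
#' @param df_offset `h - q`: equality rows carried beyond the tested
#'   inequalities; 0 for a pure inequality hypothesis.
#' @return A p-value in `[0, 1]`.
#' @export
pvalue_chibar <- function(stat, weights, df_offset = 0) {
  w <- if (inherits(weights, "chibar_weights")) weights$w else weights
  if (!is.finite(stat)) stop("statistic must be finite", call. = FALSE)
  df <- df_offset + seq_along(w) - 1
  tails <- ifelse(df == 0,
                  as.numeric(stat <= 0),
                  stats::pchisq(stat, pmax(df, 1), lower.tail = FALSE))
  if (stat <= 0) tails[df > 0] <- 1   # full mass above a non-positive value
  sum(w * tails)
}

#' F-bar mixture p-value
#'
#' `sum_i w_i P((df_offset + i) F(df_offset + i, df2) >= stat)`: the
#' statistic entering here is the unscaled F-bar form (no `1/h` factor),
#' which the degrees-of-freedom multiplier inside the mixture accounts for.
#' The zero-df component is a point mass at zero.
#'
#' @inheritParams pvalue_chibar
#' @param df2 Denominator degrees of freedom, `n - k`.
#' @return A p-value in `[0, 1]`.
#' @export
pvalue_fbar <- function(stat, weights, df_offset = 0, df2) {
  w <- if (inherits(weights, "chibar_weights")) weights$w else weights
  if (!is.finite(stat)) stop("statistic must be finite", call. = FALSE)
  if (df2 <= 0) stop("df2 must be positive", call. = FALSE)
  df1 <- df_offset + seq_along(w) - 1
  tails <- ifelse(df1 == 0,
                  as.numeric(stat <= 0),
                  stats::pf(stat / pmax(df1, 1), pmax(df1, 1), df2,
                            lower.tail = FALSE))
  if (stat <= 0) tails[df1 > 0] <- 1
  sum(w * tails)
}
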