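# Shared fixtures: all test data is built in code.

# Random regression instance with intercept + (k-1) standard-normal predictors.
random_instance <- function(n, k = 6, seed = NULL, beta = rep(0, k), sigma = 1) {
  draw <- function() {
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n, k - 1))
    y <- drop(X %*% beta) + rnorm(n, sd = sigma)
    regression_data(y, X)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Random full-row-rank constraint set.
random_constraints <- function(k, h, q = h, seed = NULL, rhs = 0) {
  draw <- function() {
    repeat {
      R <- matrix(rnorm(h * k), h, k)
      if (qr(t(R))$rank == h) break
    }
    op <- c(rep("=", h - q), rep(">=", q))
    iht_constraints(R, rhs = rhs, op = op)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Independent Monte-Carlo oracle for mixture weights: count positive
# components of the cone projection of N(0, V) draws. For diagonal V the
# projection truncates componentwise; otherwise each draw is projected by
# quadratic programming.
mc_level_probabilities <- function(V, draws, seed) {
  q <- nrow(V)
  withr::with_seed(seed, {
    Z <- matrix(rnorm(draws * q), draws, q) %*% chol(V)
    counts <- if (all(abs(V[upper.tri(V)]) < 1e-12)) {
      rowSums(Z > 0)
    } else {
      Vi <- solve(V)
      apply(Z, 1, function(z) {
        sol <- quadprog::solve.QP(Vi, drop(Vi %*% z), diag(q), rep(0, q))
        sum(sol$solution > 1e-8)
      })
    }
    tabulate(counts + 1L, nbins = q + 1L) / draws
  })
}

# Verify stationarity, primal feasibility, dual feasibility and
# complementary slackness of a constrained fit.
expect_kkt <- function(fit, tol = 1e-6) {
  cons <- fit$constraints
  d <- fit$data
  grad <- drop(crossprod(d$X, drop(d$X %*% fit$beta) - d$y))  # of 1/2||y-Xb||^2
  lam <- qr.solve(t(cons$R), grad)
  scale <- max(1, max(abs(grad)))
  # gradient lies in the row space of R'
  expect_lt(max(abs(drop(t(cons$R) %*% lam) - grad)) / scale, tol)
  slack <- drop(cons$R %*% fit$beta) - cons$rhs
  ge <- cons$op == ">="
  expect_true(all(slack[ge] > -tol))                    # primal feasibility
  expect_true(all(lam[ge] > -tol * scale))              # dual feasibility
  if (any(ge)) {                                        # complementary slackness
    expect_lt(max(abs(lam[ge] * slack[ge])) / scale, tol)
  }
}
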