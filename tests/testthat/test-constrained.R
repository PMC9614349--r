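test_that("inactive constraints leave the OLS solution untouched", {
  d <- random_instance(40, 3, seed = 1, beta = c(0, 2, 2))
  fu <- fit_ols(d)
  cons <- iht_constraints(rbind(c(0, 1, 0), c(0, 0, 1)), op = ">=")
  fi <- fit_constrained(d, cons)
  expect_equal(fi$beta, fu$beta, tolerance = 1e-8)
  expect_equal(fi$rss, fu$rss, tolerance = 1e-10)
  expect_equal(fi$fit_class, "inequality")
})

test_that("a binding sign constraint projects to the boundary", {
  # slope-only model with a clearly negative OLS slope
  x <- c(-2, -1, 0, 1, 2)
  y <- -2 * x + c(0.1, -0.1, 0, 0.1, -0.1)
  d <- regression_data(y, matrix(x, ncol = 1))
  fi <- fit_constrained(d, iht_constraints(matrix(1), op = ">="))
  expect_equal(unname(fi$beta), 0, tolerance = 1e-10)
  expect_equal(fi$active, 1L)
  expect_kkt(fi)
})

test_that("the QP solution matches a dense grid search", {
  d <- random_instance(20, 2, seed = 2, beta = c(-1, -1))
  cons <- iht_constraints(rbind(c(1, 0), c(0, 1)), rhs = c(-0.5, 0.25),
                          op = ">=")
  fi <- fit_constrained(d, cons)
  # coarse global grid, then a fine local grid around the coarse minimum
  rss_at <- function(b1, b2) {
    G <- cbind(rep(b1, each = length(b2)), rep(b2, length(b1)))
    r <- colSums((d$y - tcrossprod(d$X, G))^2)
    min(r)
  }
  b1 <- seq(-0.5, 2, by = 0.02)
  b2 <- seq(0.25, 2, by = 0.02)
  coarse <- rss_at(b1, b2)
  b1f <- seq(max(-0.5, fi$beta[1] - 0.03), fi$beta[1] + 0.03, by = 5e-4)
  b2f <- seq(max(0.25, fi$beta[2] - 0.03), fi$beta[2] + 0.03, by = 5e-4)
  fine <- rss_at(b1f, b2f)
  expect_lte(fi$rss, min(coarse, fine) + 1e-8)
  expect_equal(fi$rss, fine, tolerance = 1e-4)
  expect_kkt(fi)
})

test_that("equality projection closed form agrees with the QP route", {
  for (s in 1:10) {
    d <- random_instance(30, 5, seed = 200 + s)
    h <- sample(1:4, 1)
    cons <- random_constraints(5, h, q = 0, seed = 300 + s,
                               rhs = rnorm(h, sd = 0.2))
    fu <- fit_ols(d)
    W <- crossprod(d$X) / d$n
    bp <- equality_projection(fu$beta, W, cons)
    fe <- fit_constrained(d, cons)
    expect_equal(bp, unname(fe$beta), tolerance = 1e-8)
    expect_equal(drop(cons$R %*% bp), cons$rhs, tolerance = 1e-8)
  }
})

test_that("projection with satisfied constraints returns beta_hat unchanged", {
  d <- random_instance(25, 4, seed = 3)
  fu <- fit_ols(d)
  R <- rbind(c(0, 1, 1, 0), c(0, 0, 1, -1))
  cons <- iht_constraints(R, rhs = drop(R %*% fu$beta), op = "=")
  W <- crossprod(d$X) / d$n
  expect_equal(equality_projection(fu$beta, W, cons), unname(fu$beta),
               tolerance = 1e-10)
})

test_that("constraining a coefficient to zero is equivalent to refitting without it", {
  d <- random_instance(30, 4, seed = 4)
  cons <- iht_constraints(c(0, 1, 0, 0), op = "=")
  fe <- fit_constrained(d, cons)
  refit <- fit_ols(regression_data(d$y, d$X[, -2]))
  expect_equal(unname(fe$beta[-2]), unname(refit$beta), tolerance = 1e-8)
  expect_equal(unname(fe$beta[2]), 0, tolerance = 1e-12)
  expect_equal(fe$rss, refit$rss, tolerance = 1e-8)
})

test_that("distance_value obeys its closed form and ordering", {
  d <- random_instance(30, 6, seed = 5)
  fu <- fit_ols(d)
  W <- crossprod(d$X) / d$n
  cons <- build_constraints("R2")
  d_eq <- distance_value(fu$beta, W, cons, "eq")
  d_in <- distance_value(fu$beta, W, cons, "ineq")
  expect_gte(d_eq, d_in)
  expect_gte(d_in, 0)
  # closed form for the equality distance at rhs = 0
  Rb <- drop(cons$R %*% fu$beta)
  K <- cons$R %*% solve(W, t(cons$R))
  expect_equal(d_eq, drop(crossprod(Rb, solve(K, Rb))), tolerance = 1e-8)
  # a feasible point has zero cone distance (interior point, and idempotence
  # of the cone projection: the projected point is its own projection)
  fi <- fit_constrained(d, cons)
  expect_equal(distance_value(fi$beta, W, cons, "ineq"), 0, tolerance = 1e-10)
})

test_that("residual sums of squares nest across fit classes", {
  for (s in 1:20) {
    n <- withr::with_seed(400 + s, sample(10:80, 1))
    d <- random_instance(n, 6, seed = 500 + s)
    cons <- if (s %% 2) build_constraints("R1") else build_constraints("R2")
    fu <- fit_ols(d)
    fi <- fit_constrained(d, cons)
    fe <- fit_equality(d, cons)
    expect_lte(fu$rss, fi$rss + 1e-10)
    expect_lte(fi$rss, fe$rss + 1e-10)
    expect_kkt(fi)
    expect_kkt(fe)
  }
})

test_that("tightening an inequality bound never decreases the optimum", {
  d <- random_instance(25, 3, seed = 6)
  base <- iht_constraints(rbind(c(0, 1, 0), c(0, 0, 1)), op = ">=")
  rss <- vapply(c(0, 0.2, 0.5, 1, 2), function(b) {
    fit_constrained(d, iht_constraints(base$R, rhs = c(b, 0), op = ">="))$rss
  }, numeric(1))
  expect_true(all(diff(rss) > -1e-10))
})

test_that("mixed equality/inequality systems are solved with valid KKT points", {
  d <- random_instance(40, 5, seed = 7)
  cons <- random_constraints(5, 3, q = 2, seed = 8)
  fit <- fit_constrained(d, cons)
  expect_equal(fit$fit_class, "inequality")
  expect_kkt(fit)
  gap <- drop(cons$R %*% fit$beta) - cons$rhs
  expect_lt(abs(gap[1]), 1e-8)       # equality row holds exactly
  expect_true(all(gap[-1] > -1e-8))  # inequality rows feasible
})

test_that("constraint parsing and validation catch malformed input", {
  expect_error(iht_constraints(rbind(c(1, 1), c(2, 2))), "rank")
  expect_error(iht_constraints(matrix(1, 3, 2)), "full row rank|more constraints")
  expect_error(iht_constraints(matrix(1), op = "<="), "operators")
  cons <- iht_constraints(rbind(c(0, 1, 0), c(0, 0, 1)), op = c("=", ">="))
  expect_equal(cons$h, 2L)
  expect_equal(cons$q, 1L)
  eq <- as_equality(cons)
  expect_equal(eq$q, 0L)
})
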