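# Fits shared by several blocks.
make_fits <- function(d, cons) {
  list(u = fit_ols(d), i = fit_constrained(d, cons), e = fit_equality(d, cons))
}

test_that("classical statistics vanish when the null holds exactly", {
  d <- random_instance(30, 4, seed = 10)
  fu <- fit_ols(d)
  R <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0))
  cons <- iht_constraints(R, rhs = drop(R %*% fu$beta), op = "=")
  fe <- fit_equality(d, cons)
  expect_equal(wald_classical(fu, cons)$value, 0, tolerance = 1e-10)
  expect_equal(lrt_classical(fu, fe, "naive")$value, 0, tolerance = 1e-8)
  expect_equal(score_classical(fe)$value, 0, tolerance = 1e-8)
  expect_equal(f_classical(fu, fe, cons)$value, 0, tolerance = 1e-10)
})

test_that("t^2 equals F for a single-row hypothesis", {
  d <- random_instance(40, 6, seed = 11)
  cons <- build_constraints("R1")
  f <- make_fits(d, cons)
  tt <- t_statistic(f$u, 2)
  Fc <- f_classical(f$u, f$e, cons, "corrected")
  expect_equal(tt$value^2, Fc$value, tolerance = 1e-10)
  # and the F p-value equals the two-sided t p-value
  expect_equal(stats::pf(Fc$value, 1, d$n - d$k, lower.tail = FALSE),
               tt$pvalue, tolerance = 1e-12)
})

test_that("the two F forms and the naive LRT closed form agree", {
  for (s in 1:10) {
    d <- random_instance(35, 6, seed = 600 + s)
    cons <- if (s %% 2) build_constraints("R1") else build_constraints("R2")
    f <- make_fits(d, cons)
    for (v in c("naive", "corrected")) {
      expect_equal(f_classical(f$u, f$e, cons, v, form = "rss")$value,
                   f_classical(f$u, f$e, cons, v, form = "info")$value,
                   tolerance = 1e-8)
    }
    expect_equal(lrt_classical(f$u, f$e, "naive")$value,
                 d$n * log(f$e$rss / f$u$rss), tolerance = 1e-10)
    expect_equal(lrt_informative(f$e, f$i, "naive")$value,
                 d$n * log(f$e$rss / f$i$rss), tolerance = 1e-10)
  }
})

test_that("t-test sidedness follows the direction of the alternative", {
  d <- random_instance(25, 3, seed = 12)
  fu <- fit_ols(d)
  tt2 <- t_statistic(fu, 2, alternative = "two.sided")
  tg <- t_statistic(fu, 2, alternative = "greater")
  tl <- t_statistic(fu, 2, alternative = "less")
  expect_equal(tg$pvalue + tl$pvalue, 1)
  if (tt2$value > 0) {
    expect_equal(tg$pvalue, tt2$pvalue / 2)
  } else {
    expect_equal(tl$pvalue, tt2$pvalue / 2)
  }
  # beta_hat equal to the null value gives t = 0 and two-sided p = 1
  t0 <- t_statistic(fu, 2, null_value = fu$beta[2])
  expect_equal(t0$value, 0)
  expect_equal(t0$pvalue, 1)
  expect_error(t_statistic(fu, 9), "range")
})

test_that("informative statistics vanish when constraints do not bind", {
  d <- random_instance(30, 6, seed = 13)
  fu <- fit_ols(d)
  cons <- iht_constraints(build_constraints("R2")$R,
                          rhs = drop(build_constraints("R2")$R %*% fu$beta),
                          op = "=")
  f <- make_fits(d, cons)
  # all-equality alternative: tilde and bar fits coincide, everything is 0
  expect_equal(lrt_informative(f$e, f$i)$value, 0, tolerance = 1e-8)
  expect_equal(d_statistic(fu, cons)$value, 0, tolerance = 1e-8)
  expect_equal(score_u_statistic(f$e, f$i, f$u)$value, 0, tolerance = 1e-8)
  expect_equal(score_info_statistic(f$e, f$i, f$u)$value, 0, tolerance = 1e-8)
})

test_that("a single wrong-side constraint collapses the cone fit onto the null fit", {
  # slope pushed negative; Ha: beta1 > 0 projects to the boundary = null set
  d <- random_instance(40, 6, seed = 14, beta = c(0, -1, 0, 0, 0, 0))
  cons <- build_constraints("R1")
  f <- make_fits(d, cons)
  expect_equal(f$i$beta, f$e$beta, tolerance = 1e-8)
  expect_equal(lrt_informative(f$e, f$i, "naive")$value, 0, tolerance = 1e-8)
  expect_equal(fbar_statistic(f$e, f$i, f$u)$value, 0, tolerance = 1e-8)
  # F-bar equals max(t, 0)^2 which is 0 here
  expect_lt(t_statistic(f$u, 2)$value, 0)
})

test_that("documented algebraic equivalences hold on random instances", {
  for (s in 1:15) {
    n <- withr::with_seed(700 + s, sample(12:100, 1))
    d <- random_instance(n, 6, seed = 800 + s)
    cons <- if (s %% 2) build_constraints("R1") else build_constraints("R2")
    f <- make_fits(d, cons)
    tol <- 1e-8
    wi <- wald_informative(f$u, f$i, cons, "corrected")$value
    expect_equal(wald_informative(f$u, f$i, cons, "corrected", "vcov")$value,
                 wi, tolerance = tol)
    expect_equal(d_statistic(f$u, cons, "corrected")$value, wi, tolerance = tol)
    expect_equal(d_statistic(f$u, cons, "naive")$value,
                 wald_informative(f$u, f$i, cons, "naive")$value,
                 tolerance = tol)
    fb <- fbar_statistic(f$e, f$i, f$u, "corrected", "rss")$value
    expect_equal(fbar_statistic(f$e, f$i, f$u, "corrected", "info")$value,
                 fb, tolerance = tol)
    si <- score_info_statistic(f$e, f$i, f$u, "corrected", "info")$value
    expect_equal(score_info_statistic(f$e, f$i, f$u, "corrected", "robertson")$value,
                 si, tolerance = tol)
    expect_equal(score_info_statistic(f$e, f$i, f$u, "corrected", "vcov")$value,
                 si, tolerance = tol)
    # F-bar (corrected) coincides with the corrected informative Wald
    expect_equal(fb, wi, tolerance = tol)
  }
})

test_that("score_u matches an independent transcription on a small instance", {
  # n = 6, k = 2, one inequality on the slope — every matrix is written out
  # from the defining formula, not through the package helpers
  d <- random_instance(6, 2, seed = 15, beta = c(0, -0.8))
  cons <- iht_constraints(c(0, 1), op = ">=")
  f <- make_fits(d, cons)
  n <- d$n; k <- d$k
  W <- crossprod(d$X) / n
  s2tc <- f$i$rss / (n - k)
  s2bc <- f$e$rss / (n - (k - 1))
  St <- crossprod(d$X, d$y - d$X %*% f$i$beta) / s2tc
  Sb <- crossprod(d$X, d$y - d$X %*% f$e$beta) / s2bc
  U <- cons$R %*% solve(W) %*% (St - Sb)
  s2hc <- f$u$rss / (n - k)
  expected <- drop(t(U) %*% solve(cons$R %*% solve(W) %*% t(cons$R)) %*% U) /
    (n * s2hc)
  expect_equal(score_u_statistic(f$e, f$i, f$u, "corrected")$value, expected,
               tolerance = 1e-10)
})

test_that("score and Wald agree asymptotically under the null", {
  d <- random_instance(10000, 6, seed = 16)
  cons <- build_constraints("R1")
  f <- make_fits(d, cons)
  w <- wald_classical(f$u, cons, "naive")$value
  s <- score_classical(f$e, "naive")$value
  expect_equal(s / w, 1, tolerance = 0.05)
})

test_that("mismatched fits are rejected", {
  d1 <- random_instance(20, 3, seed = 17)
  d2 <- random_instance(20, 3, seed = 18)
  cons <- iht_constraints(c(0, 1, 0), op = ">=")
  f1u <- fit_ols(d1)
  f2e <- fit_equality(d2, cons)
  expect_error(lrt_classical(f1u, f2e), "same data")
  cons2 <- iht_constraints(c(0, 0, 1), op = ">=")
  fi <- fit_constrained(d1, cons)
  fe2 <- fit_equality(d1, cons2)
  expect_error(lrt_informative(fe2, fi), "different constraint")
})

test_that("iht_test returns a tidy table with coherent p-values", {
  d <- random_instance(50, 6, seed = 19, beta = c(0, 0.5, 0, 0, 0, 0))
  res <- iht_test(data.frame(y = d$y, d$X[, -1]), build_constraints("R1"),
                  statistics = c("fbar", "wald_info", "lrt", "t", "f"),
                  version = "corrected")
  expect_s3_class(res, "tbl_df")
  expect_equal(nrow(res), 5)
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))
  # h = 1 bridge: F-bar p-value equals one-sided t p-value for positive t
  tv <- res$value[res$statistic == "t"]
  if (tv > 0) {
    expect_equal(res$pvalue[res$statistic == "fbar"],
                 res$pvalue[res$statistic == "t"], tolerance = 1e-10)
  }
  # naive and corrected both computed on request
  res2 <- iht_test(data.frame(y = d$y, d$X[, -1]), build_constraints("R1"),
                   statistics = "wald_info", version = c("naive", "corrected"))
  expect_equal(nrow(res2), 2)
  expect_gt(res2$value[res2$version == "naive"],
            res2$value[res2$version == "corrected"])
})
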