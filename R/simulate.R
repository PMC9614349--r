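# Monte-Carlo study harness: synthetic designs, null/alternative responses,
# and type-I / type-II error tables.

#' Default statistic set for the error-rate studies
#'
#' The pairing used in the source literature: the naive-variance
#' informative Wald with chi-bar-squared p-values, the corrected
#' informative Wald/LRT/score statistics with chi-bar-squared p-values, the
#' F-bar statistic with F-bar p-values, and the exact classical F test.
#'
#' @return A tibble with columns `statistic`, `version`, `distribution`.
#' @export
default_study_statistics <- function() {
  tibble::tibble(
    statistic = c("lrt", "wald_info", "wald_info", "score_u",
                  "score_nullinfo", "score_info", "fbar", "f"),
    version = c("corrected", "naive", "corrected", "corrected",
                "corrected", "corrected", "corrected", "corrected"),
    distribution = c("chibar", "chibar", "chibar", "chibar",
                     "chibar", "chibar", "fbar", "default")
  )
}

#' Configuration of a Monte-Carlo error-rate study
#'
#' @param n_grid Sample sizes.
#' @param f2_grid Cohen effect sizes `f^2 = R^2 / (1 - R^2)` for the
#'   type-II (power) study.
#' @param reps Replications per cell.
#' @param alpha Rejection level.
#' @param constraint_id `"R1"` (single inequality on `beta1`) or `"R2"`
#'   (inequalities on all five slopes); see [build_constraints()].
#' @param statistics Tibble with columns `statistic`, `version`,
#'   `distribution` (`"default"`, `"chibar"` or `"fbar"`); defaults to
#'   [default_study_statistics()].
#' @param seed Master seed; every cell derives its own seeds from it.
#' @param design_mode `"redrawn_per_rep"` draws a fresh design matrix for
#'   every replication (default); `"fixed_per_n"` reuses one design per
#'   cell.
#' @param p Number of predictors (besides the intercept).
#' @param beta Slope vector under the alternative (length `p`).
#' @return An object of class `iht_study_config`.
#' @export
study_config <- function(n_grid = c(10, 25, 50, 100, 500, 1000, 2000, 10000),
                         f2_grid = c(0.02, 0.10, 0.35),
                         reps = 1000,
                         alpha = 0.05,
                         constraint_id = c("R1", "R2"),
                         statistics = default_study_statistics(),
                         seed = 1L,
                         design_mode = c("redrawn_per_rep", "fixed_per_n"),
                         p = 5,
                         beta = rep(0.1, p)) {
  constraint_id <- match.arg(constraint_id)
  design_mode <- match.arg(design_mode)
  statistics <- tibble::as_tibble(statistics)
  stopifnot(all(c("statistic", "version", "distribution") %in% names(statistics)),
            reps >= 1, alpha > 0, alpha < 1, all(n_grid > p + 1),
            length(beta) == p)
  structure(
    list(n_grid = as.integer(n_grid), f2_grid = f2_grid,
         reps = as.integer(reps), alpha = alpha,
         constraint_id = constraint_id, statistics = statistics,
         seed = as.integer(seed), design_mode = design_mode,
         p = as.integer(p), beta = beta),
    class = "iht_study_config"
  )
}

#' Generate an orthogonalised standard-normal design matrix
#'
#' Draws `n x p` standard normals, centres the columns, orthogonalises them
#' and rescales each to unit sample standard deviation, then prepends an
#' intercept column. The predictor block therefore has exactly zero sample
#' means and pairwise correlations.
#'
#' @param n Sample size (must exceed `p + 1`).
#' @param p Number of predictors.
#' @param seed Optional seed; the matrix is deterministic given it.
#' @return An `n x (p + 1)` matrix.
#' @export
generate_design <- function(n, p = 5, seed = NULL) {
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  draw <- function() {
    Z <- matrix(stats::rnorm(n * p), n, p)
    Z <- sweep(Z, 2, colMeans(Z))
    Q <- qr.Q(qr(Z))
    Q <- sweep(Q, 2, colMeans(Q))
    Q <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")
    colnames(Q) <- paste0("x", seq_len(p))
    cbind(`(Intercept)` = 1, Q)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Error variance implied by an effect size
#'
#' For standardized predictors with correlation matrix `corX` and slopes
#' `beta`, the explained variance is `beta' corX beta` and the error
#' variance that yields determination coefficient `R^2 = f2 / (1 + f2)` is
#' `(beta' corX beta) (1 - R^2) / R^2`, i.e. `(beta' corX beta) / f2`.
#'
#' @param beta Slope vector (excluding the intercept).
#' @param corX Correlation matrix of the predictors.
#' @param f2 Positive effect size.
#' @return The error variance, a positive scalar.
#' @export
error_variance_from_f2 <- function(beta, corX, f2) {
  if (f2 <= 0) stop("f2 must be positive", call. = FALSE)
  drop(crossprod(beta, corX %*% beta)) / f2
}

#' Pure-noise response for type-I studies
#'
#' @param n Sample size.
#' @param seed Optional seed.
#' @return A standard-normal vector independent of any design.
#' @export
generate_null_response <- function(n, seed = NULL) {
  if (is.null(seed)) stats::rnorm(n) else withr::with_seed(seed, stats::rnorm(n))
}

#' Response under the order-restricted alternative
#'
#' `y = X c(0, beta) + e` with iid Gaussian errors whose variance is set by
#' [error_variance_from_f2()] from the sample correlation of the predictor
#' block, so that the population determination coefficient matches the
#' requested effect size.
#'
#' @param X Design matrix including the intercept column.
#' @param beta Slope vector (the intercept is fixed at zero).
#' @param f2 Positive effect size.
#' @param seed Optional seed.
#' @return A response vector of length `nrow(X)`.
#' @export
generate_alt_response <- function(X, beta, f2, seed = NULL) {
  p <- ncol(X) - 1
  stopifnot(length(beta) == p)
  corX <- stats::cor(X[, -1, drop = FALSE])
  s2 <- error_variance_from_f2(beta, corX, f2)
  mu <- drop(X %*% c(0, beta))
  draw <- function() mu + stats::rnorm(nrow(X), sd = sqrt(s2))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @keywords internal
simulate_cell <- function(cfg, n, f2, cons, cell_seed) {
  spec <- cfg$statistics
  ns <- nrow(spec)
  labels <- paste(spec$statistic, spec$version, spec$distribution, sep = ".")
  seeds <- withr::with_seed(cell_seed,
                            matrix(sample.int(.Machine$integer.max - 1L,
                                              cfg$reps * 2L),
                                   ncol = 2))
  X_fixed <- if (cfg$design_mode == "fixed_per_n") {
    generate_design(n, cfg$p, seed = cell_seed)
  }
  pmat <- matrix(NA_real_, cfg$reps, ns, dimnames = list(NULL, labels))
  failed <- 0L
  for (r in seq_len(cfg$reps)) {
    res <- tryCatch({
      X <- if (is.null(X_fixed)) generate_design(n, cfg$p, seed = seeds[r, 1]) else X_fixed
      y <- if (is.na(f2)) generate_null_response(n, seed = seeds[r, 2])
           else generate_alt_response(X, cfg$beta, f2, seed = seeds[r, 2])
      data <- regression_data(y, X)
      rep_pvalues(data, cons, spec)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else pmat[r, ] <- res
  }
  list(pvalues = pmat, failed = failed, seed = cell_seed)
}

#' @keywords internal
rep_pvalues <- function(data, cons, spec) {
  fit_u <- fit_ols(data)
  fit_in <- fit_constrained(data, cons)
  fit_eq <- fit_equality(data, cons)
  wts <- if (cons$q > 0) chibar_weights(constraint_kernel(data, cons)) else NULL
  df_offset <- cons$h - cons$q
  df2 <- data$n - data$k
  out <- numeric(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    row <- compute_statistic(spec$statistic[i], spec$version[i], data, cons,
                             fit_u, fit_in, fit_eq)
    out[i] <- apply_pvalue(row, spec$statistic[i], spec$distribution[i], wts,
                           df_offset, df2)$pvalue
  }
  out
}

#' @keywords internal
run_study <- function(cfg, f2_values, keep_pvalues = FALSE) {
  cons <- build_constraints(cfg$constraint_id, cfg$p + 1)
  cells <- expand.grid(n = cfg$n_grid, f2 = f2_values,
                       KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- withr::with_seed(cfg$seed,
                                 sample.int(.Machine$integer.max - 1L,
                                            nrow(cells)))
  results <- vector("list", nrow(cells))
  kept <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- simulate_cell(cfg, cells$n[i], cells$f2[i], cons, cell_seeds[i])
    ok <- stats::complete.cases(cell$pvalues)
    rej <- colSums(cell$pvalues[ok, , drop = FALSE] < cfg$alpha)
    nrep <- sum(ok)
    rate <- rej / nrep
    results[[i]] <- tibble::tibble(
      n = cells$n[i],
      f2 = cells$f2[i],
      statistic = cfg$statistics$statistic,
      version = cfg$statistics$version,
      distribution = cfg$statistics$distribution,
      rejection_rate = unname(rate),
      rejections = unname(rej),
      reps = nrep,
      mc_se = sqrt(unname(rate) * (1 - unname(rate)) / nrep),
      n_failed = cell$failed,
      seed = cell$seed
    )
    if (keep_pvalues) {
      kept[[paste0("n", cells$n[i], "_f2", cells$f2[i])]] <- cell$pvalues
    }
  }
  out <- dplyr::bind_rows(results)
  class(out) <- c("iht_sim", class(out))
  attr(out, "config") <- cfg
  if (keep_pvalues) attr(out, "pvalues") <- kept
  out
}

#' Type-I error study
#'
#' For every sample size in the configuration, generates pure-noise
#' responses, applies each requested (statistic, version, distribution)
#' triple and reports the fraction of replications with p-value below
#' `alpha`, together with the binomial Monte-Carlo standard error.
#'
#' @param cfg An [study_config()] object.
#' @param keep_pvalues Keep the per-replication p-value matrices as
#'   attribute `"pvalues"` (one matrix per cell).
#' @return A tibble of class `iht_sim`, one row per
#'   (n, statistic, version, distribution) cell (`f2` is `NA`).
#' @export
run_type1_study <- function(cfg, keep_pvalues = FALSE) {
  run_study(cfg, NA_real_, keep_pvalues)
}

#' Type-II error study
#'
#' As [run_type1_study()], but responses are drawn under the alternative
#' (all slopes at their configured values, error variance set by the
#' effect size); reports `type2_error = 1 - rejection_rate`.
#'
#' @inheritParams run_type1_study
#' @return A tibble of class `iht_sim` with an additional `type2_error`
#'   column, one row per (n, f2, statistic, version, distribution) cell.
#' @export
run_type2_study <- function(cfg, keep_pvalues = FALSE) {
  out <- run_study(cfg, cfg$f2_grid, keep_pvalues)
  out$type2_error <- 1 - out$rejection_rate
  out
}

#' Line plot of type-II error against sample size
#'
#' One panel per effect size, one line per statistic/version/distribution
#' triple, mirroring the usual presentation of power studies.
#'
#' @param object An `iht_sim` tibble from [run_type2_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iht_sim <- function(object, ...) {
  if (!"type2_error" %in% names(object)) {
    object$type2_error <- 1 - object$rejection_rate
  }
  object$test <- paste(object$statistic, object$version, object$distribution,
                       sep = ".")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n, y = .data$type2_error,
                               colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~f2, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size n", y = "type II error rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.iht_sim
#' @export
plot_type2 <- function(object, ...) autoplot.iht_sim(object, ...)
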