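# One-stop informative hypothesis test on a data frame.

iht_statistic_names <- c(
  "lrt", "wald_info", "wald_vcov", "d", "fbar",
  "score_u", "score_nullinfo", "score_info", "score_vcov",
  "f", "t", "wald", "score"
)

#' @keywords internal
default_distribution <- function(statistic) {
  switch(statistic,
    fbar = "fbar",
    f = "f",
    t = "t",
    wald = , score = "chisq",
    lrt = , wald_info = , wald_vcov = , d = ,
    score_u = , score_nullinfo = , score_info = , score_vcov = "chibar",
    stop("unknown statistic: ", statistic, call. = FALSE)
  )
}

#' Informative hypothesis tests for a linear regression
#'
#' Fits the unconstrained, inequality-constrained and equality-constrained
#' least-squares models implied by `constraints`, computes the requested
#' test statistics and attaches p-values. Classical statistics (`wald`,
#' `score`, `f`, `t`) test `H0: R beta = rhs` against its two-sided
#' complement; informative statistics (`lrt`, `wald_info`, `wald_vcov`,
#' `d`, `fbar`, `score_u`, `score_nullinfo`, `score_info`, `score_vcov`)
#' test `H0` against the order-restricted alternative `R beta >= rhs` and
#' draw their p-values from the chi-bar-squared or F-bar mixture whose
#' weights come from the constraint-cone geometry. When the constraint set
#' contains no inequality rows, `lrt` denotes the classical likelihood-ratio
#' test.
#'
#' @param data A data frame (first column the response; see
#'   [as_regression_data()]) or an `iht_data` object.
#' @param constraints An [iht_constraints] object, or a matrix interpreted
#'   as inequality rows with zero right-hand side.
#' @param statistics Character vector of statistic names (see above).
#' @param version `"corrected"`, `"naive"` or both.
#' @param distribution `"default"` uses the pairing of the source
#'   literature (F-bar p-values for the F-bar statistic, chi-bar-squared
#'   for the other informative statistics, exact F/t/chi-squared for the
#'   classical ones); `"chibar"` or `"fbar"` force that mixture for every
#'   informative statistic.
#' @param weight_method,mc_draws,seed Passed to [chibar_weights()].
#' @param response Response column (name or index) when `data` is a data
#'   frame.
#' @return A tibble with one row per (statistic, version): columns
#'   `statistic`, `version`, `value`, `distribution`, `pvalue`, `h`, `q`,
#'   `n`, `k`, and a list column `weights` holding the mixture weights for
#'   mixture-distributed rows. The weight object is also attached as
#'   attribute `"weights"`.
#' @examples
#' set.seed(7)
#' df <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40))
#' iht_test(df, iht_constraints(rbind(c(0, 1, 0), c(0, 0, 1))),
#'          statistics = c("fbar", "wald_info", "f"))
#' @export
iht_test <- function(data, constraints,
                     statistics = c("fbar", "wald_info", "lrt", "score_u",
                                    "score_nullinfo", "score_info", "f"),
                     version = "corrected",
                     distribution = c("default", "chibar", "fbar"),
                     weight_method = "auto", mc_draws = 1e5, seed = NULL,
                     response = 1) {
  if (is.data.frame(data)) data <- as_regression_data(data, response)
  if (is.matrix(constraints) || is.numeric(constraints)) {
    constraints <- iht_constraints(constraints)
  }
  distribution <- match.arg(distribution)
  bad <- setdiff(statistics, iht_statistic_names)
  if (length(bad) > 0) stop("unknown statistic(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  stopifnot(all(version %in% c("naive", "corrected")))

  cons <- constraints
  fit_u <- fit_ols(data)
  fit_in <- fit_constrained(data, cons)
  fit_eq <- fit_equality(data, cons)

  wts <- NULL
  if (cons$q > 0) {
    wts <- chibar_weights(constraint_kernel(data, cons),
                          method = weight_method, mc_draws = mc_draws,
                          seed = seed)
  }
  df_offset <- cons$h - cons$q
  df2 <- data$n - data$k

  rows <- list()
  for (st in statistics) {
    for (v in version) {
      row <- compute_statistic(st, v, data, cons, fit_u, fit_in, fit_eq)
      rows[[length(rows) + 1]] <- apply_pvalue(row, st, distribution, wts,
                                               df_offset, df2)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$weights <- lapply(out$distribution, function(d) {
    if (d %in% c("chibar", "fbar") && !is.null(wts)) wts$w else NULL
  })
  attr(out, "weights") <- wts
  out
}

#' @keywords internal
compute_statistic <- function(st, v, data, cons, fit_u, fit_in, fit_eq) {
  switch(st,
    wald = wald_classical(fit_u, cons, v),
    score = score_classical(fit_eq, v),
    f = f_classical(fit_u, fit_eq, cons, v),
    t = {
      idx <- single_coefficient_index(cons)
      alt <- if (cons$q == 1) {
        if (cons$R[1, idx] > 0) "greater" else "less"
      } else "two.sided"
      t_statistic(fit_u, idx, cons$rhs[1] / cons$R[1, idx], alternative = alt)
    },
    lrt = if (cons$q == 0) lrt_classical(fit_u, fit_eq, v)
          else lrt_informative(fit_eq, fit_in, v),
    wald_info = wald_informative(fit_u, fit_in, cons, v, form = "info"),
    wald_vcov = wald_informative(fit_u, fit_in, cons, v, form = "vcov"),
    d = d_statistic(fit_u, cons, v),
    fbar = fbar_statistic(fit_eq, fit_in, fit_u, v, form = "rss"),
    score_u = score_u_statistic(fit_eq, fit_in, fit_u, v),
    score_nullinfo = score_nullinfo_statistic(fit_eq, fit_in, v),
    score_info = score_info_statistic(fit_eq, fit_in, fit_u, v, form = "info"),
    score_vcov = score_info_statistic(fit_eq, fit_in, fit_u, v, form = "vcov")
  )
}

#' @keywords internal
single_coefficient_index <- function(cons) {
  nz <- which(cons$R[1, ] != 0)
  if (cons$h != 1 || length(nz) != 1) {
    stop("the t statistic requires a single constraint row on a single ",
         "coefficient", call. = FALSE)
  }
  nz
}

#' @keywords internal
apply_pvalue <- function(row, st, distribution, wts, df_offset, df2) {
  if (st == "t") return(row)                       # p-value already attached
  if (st %in% c("wald", "score", "f")) {
    if (st == "f") {
      row$distribution <- sprintf("f(%d,%d)", row$h, df2)
      row$pvalue <- stats::pf(row$value, row$h, df2, lower.tail = FALSE)
    } else {
      row$distribution <- sprintf("chisq(%d)", row$h)
      row$pvalue <- stats::pchisq(row$value, row$h, lower.tail = FALSE)
    }
    return(row)
  }
  if (row$q == 0) {                                # classical LRT
    row$distribution <- sprintf("chisq(%d)", row$h)
    row$pvalue <- stats::pchisq(row$value, row$h, lower.tail = FALSE)
    return(row)
  }
  dist <- if (distribution == "default") default_distribution(st) else distribution
  if (dist == "chibar") {
    row$distribution <- "chibar"
    row$pvalue <- pvalue_chibar(row$value, wts, df_offset)
  } else {
    row$distribution <- "fbar"
    row$pvalue <- pvalue_fbar(row$value, wts, df_offset, df2)
  }
  row
}
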