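#' Assemble a response/design pair for constrained regression
#'
#' Bundles a response vector and a fixed design matrix, checking the model
#' assumptions that the inference machinery relies on: at least as many
#' observations as coefficients and a design of full column rank (the rank
#' check fails when the condition number exceeds `1e10`).
#'
#' @param y Numeric response vector of length `n`.
#' @param X Numeric design matrix, `n` rows; by convention the first column
#'   is the intercept column of ones.
#' @return An object of class `iht_data`: list with `y`, `X`, `n` and `k`.
#' @export
regression_data <- function(y, X) {
  y <- as.numeric(y)
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values are not supported", call. = FALSE)
  if (n < k) stop("need n >= k (more observations than coefficients)", call. = FALSE)
  d <- svd(X, nu = 0, nv = 0)$d
  if (d[k] <= 0 || d[1] / d[k] > 1e10) {
    stop("design matrix is (numerically) rank deficient; ",
         "full column rank is a model assumption", call. = FALSE)
  }
  structure(list(y = y, X = X, n = n, k = k), class = "iht_data")
}

#' Coerce a data frame to regression data
#'
#' The first column (or the column named by `response`) is the response; all
#' remaining columns are predictors. An intercept column of ones is
#' prepended unless one of the predictor columns already is exactly a column
#' of ones.
#'
#' @param data A data frame.
#' @param response Column name or index of the response; defaults to the
#'   first column.
#' @return An `iht_data` object.
#' @export
as_regression_data <- function(data, response = 1) {
  data <- as.data.frame(data)
  if (is.character(response)) {
    response <- match(response, names(data))
    if (is.na(response)) stop("response column not found", call. = FALSE)
  }
  y <- data[[response]]
  Xdf <- data[, -response, drop = FALSE]
  if (!all(vapply(Xdf, is.numeric, logical(1))) || !is.numeric(y)) {
    stop("all columns must be numeric", call. = FALSE)
  }
  X <- as.matrix(Xdf)
  has_ones <- ncol(X) > 0 && any(apply(X, 2, function(col) all(col == 1)))
  if (!has_ones) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  regression_data(y, X)
}

#' Read regression data from a delimited text file
#'
#' Expects a header row; the first column is the response and the remaining
#' columns are predictors (an intercept is added via [as_regression_data()]).
#'
#' @param path Path to a CSV file.
#' @return An `iht_data` object.
#' @export
read_regression_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_regression_data(df)
}

#' @export
print.iht_data <- function(x, ...) {
  cat(sprintf("<iht_data: n = %d, k = %d>\n", x$n, x$k))
  invisible(x)
}
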