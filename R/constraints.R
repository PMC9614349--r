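#' Linear constraint sets on regression coefficients
#'
#' An informative hypothesis places linear equality or inequality constraints
#' on the coefficients of a regression model. Each constraint is one row of a
#' matrix `R` together with a right-hand side and an operator, so that the
#' hypothesis reads `R %*% beta (op) rhs` row by row, e.g.
#' `Ha: beta1 > 0 | beta2 > 0`. The corresponding null hypothesis replaces
#' every operator by equality.
#'
#' @param R Numeric constraint matrix with one row per constraint and one
#'   column per regression coefficient (including the intercept). Must have
#'   full row rank.
#' @param rhs Right-hand-side vector, recycled to `nrow(R)`. Defaults to 0,
#'   the usual setting for directional hypotheses.
#' @param op Character vector of per-row operators, `"="` or `">="`,
#'   recycled to `nrow(R)`.
#'
#' @return An object of class `iht_constraints`: a list with elements `R`,
#'   `rhs`, `op`, `h` (number of rows) and `q` (number of inequality rows).
#' @examples
#' # Ha: beta1 > 0 in a model with intercept + 5 predictors
#' iht_constraints(matrix(c(0, 1, 0, 0, 0, 0), nrow = 1))
#' @export
iht_constraints <- function(R, rhs = 0, op = ">=") {
  if (!is.matrix(R)) R <- matrix(R, nrow = 1)
  storage.mode(R) <- "double"
  h <- nrow(R)
  k <- ncol(R)
  if (h < 1) stop("constraint matrix must have at least one row", call. = FALSE)
  if (h > k) stop("more constraints than coefficients: R cannot have full row rank", call. = FALSE)
  if (qr(t(R))$rank < h) {
    stop("constraint matrix R is row-rank deficient", call. = FALSE)
  }
  rhs <- rep_len(as.numeric(rhs), h)
  if (any(!is.finite(rhs))) stop("non-finite right-hand side", call. = FALSE)
  op <- rep_len(as.character(op), h)
  op[op %in% c("==", "eq")] <- "="
  op[op %in% c("ge", ">")] <- ">="
  if (!all(op %in% c("=", ">="))) {
    stop("operators must be \"=\" or \">=\"", call. = FALSE)
  }
  structure(
    list(R = R, rhs = rhs, op = op, h = h, q = sum(op == ">=")),
    class = "iht_constraints"
  )
}

#' @export
print.iht_constraints <- function(x, ...) {
  cat(sprintf("<iht_constraints: %d row(s), %d inequality>\n", x$h, x$q))
  for (i in seq_len(x$h)) {
    cat(" ", paste(format(x$R[i, ], trim = TRUE), collapse = " "),
        x$op[i], format(x$rhs[i]), "\n")
  }
  invisible(x)
}

#' Replace every constraint operator by equality
#'
#' The equality-constrained ("null") counterpart of a constraint set: the
#' same rows `R` and right-hand side, with all operators set to `"="`.
#'
#' @param cons An [iht_constraints] object.
#' @return An [iht_constraints] object with `q = 0`.
#' @export
as_equality <- function(cons) {
  stopifnot(inherits(cons, "iht_constraints"))
  iht_constraints(cons$R, cons$rhs, "=")
}

#' Benchmark constraint matrices for a six-coefficient regression
#'
#' Two standard hypotheses for a model with an intercept and five predictors:
#' `"R1"` is the single directional constraint `Ha: beta1 > 0`, and `"R2"`
#' constrains all five slopes, `Ha: beta1 > 0 | ... | beta5 > 0`, i.e. an
#' identity block on the slope columns.
#'
#' @param which `"R1"` or `"R2"`.
#' @param k Number of columns (coefficients); only `k = 6` is supported.
#' @return An [iht_constraints] object with `rhs = 0` and all rows `">="`.
#' @export
build_constraints <- function(which = c("R1", "R2"), k = 6) {
  which <- match.arg(which)
  if (k != 6) stop("only k = 6 is supported for the benchmark hypotheses", call. = FALSE)
  R <- switch(which,
    R1 = matrix(c(0, 1, 0, 0, 0, 0), nrow = 1),
    R2 = cbind(0, diag(5))
  )
  iht_constraints(R, rhs = 0, op = ">=")
}

#' Read a constraint set from a plain-text specification
#'
#' One constraint per line: `k` coefficients, an operator token (`=` or
#' `>=`), and a right-hand-side value, whitespace separated. Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path Path to the specification file.
#' @return An [iht_constraints] object.
#' @examples
#' f <- tempfile()
#' writeLines(c("0 1 0 0 0 0 >= 0", "0 0 1 0 0 0 >= 0"), f)
#' read_constraints(f)
#' @export
read_constraints <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no constraint rows found in ", path, call. = FALSE)
  parsed <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    iop <- which(tok %in% c("=", "==", ">=", ">"))
    if (length(iop) != 1 || iop != length(tok) - 1) {
      stop("malformed constraint line (expect <k coefs> <op> <rhs>): ", ln,
           call. = FALSE)
    }
    list(coef = as.numeric(tok[seq_len(iop - 1)]),
         op = tok[iop],
         rhs = as.numeric(tok[iop + 1]))
  })
  kk <- lengths(lapply(parsed, `[[`, "coef"))
  if (length(unique(kk)) != 1) {
    stop("constraint rows have inconsistent numbers of coefficients", call. = FALSE)
  }
  iht_constraints(
    R = do.call(rbind, lapply(parsed, `[[`, "coef")),
    rhs = vapply(parsed, `[[`, numeric(1), "rhs"),
    op = vapply(parsed, `[[`, character(1), "op")
  )
}
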