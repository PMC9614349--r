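#' Constrained least-squares fit via quadratic programming
#'
#' Minimises `||y - X beta||^2` subject to `R beta (op) rhs`, using the dual
#' active-set method of Goldfarb and Idnani (`quadprog::solve.QP`). Because
#' `X` has full column rank the objective is strictly convex and the
#' minimiser is unique. The fit class is `"equality"` when every row is an
#' equality and `"inequality"` otherwise; the class determines the
#' denominator of the corrected residual variance (see
#' [residual_variance()]).
#'
#' @param data An `iht_data` object or data frame.
#' @param cons An [iht_constraints] object.
#' @return An `iht_fit` object carrying the active constraint set and the
#'   Lagrange multipliers in original row order.
#' @examples
#' set.seed(1)
#' d <- regression_data(rnorm(20), cbind(1, rnorm(20)))
#' fit_constrained(d, iht_constraints(c(0, 1), op = ">="))
#' @export
fit_constrained <- function(data, cons) {
  if (is.data.frame(data)) data <- as_regression_data(data)
  stopifnot(inherits(data, "iht_data"), inherits(cons, "iht_constraints"))
  if (ncol(cons$R) != data$k) {
    stop("constraint matrix has ", ncol(cons$R), " columns but the design has ",
         data$k, " coefficients", call. = FALSE)
  }
  ord <- order(cons$op != "=")           # equality rows first for solve.QP
  Ro <- cons$R[ord, , drop = FALSE]
  bo <- cons$rhs[ord]
  meq <- sum(cons$op == "=")
  sol <- tryCatch(
    quadprog::solve.QP(
      Dmat = crossprod(data$X),
      dvec = drop(crossprod(data$X, data$y)),
      Amat = t(Ro),
      bvec = bo,
      meq = meq
    ),
    error = function(e) {
      stop("constrained least-squares problem could not be solved: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  beta <- sol$solution
  lag <- numeric(cons$h)
  lag[ord] <- sol$Lagrangian
  viol <- drop(cons$R %*% beta) - cons$rhs
  act <- which(abs(viol) < 1e-8 * (1 + abs(cons$rhs)))
  fit_class <- if (meq == cons$h) "equality" else "inequality"
  new_iht_fit(data, beta, fit_class, h = cons$h, cons = cons,
              active = act, lagrange = lag)
}

#' Equality-constrained fit
#'
#' Convenience wrapper: fits with every constraint row forced to equality.
#' This is both the null-hypothesis fit of informative testing and the
#' restricted fit of classical testing.
#'
#' @inheritParams fit_constrained
#' @return An `iht_fit` with `fit_class = "equality"`.
#' @export
fit_equality <- function(data, cons) {
  fit_constrained(data, as_equality(cons))
}

#' Closed-form projection onto an equality constraint set
#'
#' For an all-equality system the constrained minimiser has the closed form
#' `beta_hat - W^-1 R' (R W^-1 R')^-1 (R beta_hat - rhs)`, the projection of
#' the unconstrained estimate onto the affine set `{R beta = rhs}` in the
#' metric of `W`. Provided as an independent check on the quadratic
#' programming route.
#'
#' @param beta_hat Unconstrained coefficient estimate.
#' @param W Positive-definite weight matrix, typically `X'X / n`.
#' @param cons An [iht_constraints] object; all rows must be equalities
#'   (operators are ignored, the rows are treated as equalities).
#' @return The projected coefficient vector.
#' @export
equality_projection <- function(beta_hat, W, cons) {
  stopifnot(inherits(cons, "iht_constraints"))
  R <- cons$R
  WiRt <- solve(W, t(R))
  K <- R %*% WiRt
  gap <- drop(R %*% beta_hat) - cons$rhs
  drop(beta_hat - WiRt %*% solve(K, gap))
}

#' Squared weighted distance from the unconstrained estimate to a
#' constraint set
#'
#' Minimises `(beta_hat - beta)' W (beta_hat - beta)` over `{R beta = rhs}`
#' (`mode = "eq"`) or over the polyhedral cone `{R beta >= rhs}` with any
#' equality rows of `cons` kept as equalities (`mode = "ineq"`), treating
#' `beta_hat` and `W` as known constants. These are the two distances the
#' distance statistic differences; the equality distance can never be
#' smaller than the cone distance.
#'
#' @inheritParams equality_projection
#' @param mode `"eq"` or `"ineq"`.
#' @return The minimised quadratic, a non-negative scalar.
#' @export
distance_value <- function(beta_hat, W, cons, mode = c("ineq", "eq")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cons, "iht_constraints"))
  use <- if (mode == "eq") as_equality(cons) else cons
  ord <- order(use$op != "=")
  Ro <- use$R[ord, , drop = FALSE]
  bo <- use$rhs[ord]
  sol <- quadprog::solve.QP(
    Dmat = 2 * W,
    dvec = 2 * drop(W %*% beta_hat),
    Amat = t(Ro),
    bvec = bo,
    meq = sum(use$op == "=")
  )
  delta <- beta_hat - sol$solution
  max(0, drop(crossprod(delta, W %*% delta)))
}
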