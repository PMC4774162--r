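#' Univariate half-thresholding operator
#'
#' Closed-form minimizer of the scalar L1/2-penalized problem
#' g(b) = (b - omega)^2 + lambda * |b|^(1/2).
#' For |omega| above the threshold [threshold_boundary()] =
#' 54^(1/3)/4 * lambda^(2/3) the minimizer is
#' (2/3) * omega * (1 + cos(2 * (pi - phi) / 3)) with
#' phi = arccos((lambda / 8) * (|omega| / 3)^(-3/2)); at or below the
#' threshold (including exact equality) it is 0. The operator is odd in
#' omega and shrinks: |output| <= |omega|, with equality iff lambda = 0.
#'
#' Penalty calibration: because the quadratic term carries no 1/2, the
#' minimizer of the half-weighted form (1/2)(b - omega)^2 + L * |b|^(1/2)
#' is `half_threshold(omega, 2 * L)` — the identity the coordinate-descent
#' solver uses for its exact per-coordinate update.
#'
#' @param omega Numeric vector of unpenalized univariate solutions.
#' @param lambda Penalty weight(s), >= 0 (recycled against `omega`).
#' @return Numeric vector of thresholded values.
#' @export
#' @examples
#' half_threshold(1, 0)      # identity at lambda = 0
#' half_threshold(0.1, 1)    # below the boundary: 0
#' threshold_boundary(1)     # ~0.9449
half_threshold <- function(omega, lambda) {
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  k <- pmax(length(omega), length(lambda))
  omega <- rep_len(omega, k)
  lambda <- rep_len(lambda, k)
  out <- numeric(k)
  a <- abs(omega)
  nz <- a > threshold_boundary(lambda)
  if (any(nz)) {
    arg <- pmin(1, (lambda[nz] / 8) * (a[nz] / 3)^(-3 / 2))
    phi <- acos(arg)
    out[nz] <- (2 / 3) * omega[nz] * (1 + cos(2 * (pi - phi) / 3))
  }
  out
}

#' Half-thresholding boundary
#'
#' The smallest |omega| at which [half_threshold()] returns a nonzero value:
#' 54^(1/3)/4 * lambda^(2/3). Below or at this boundary the scalar problem
#' (b - omega)^2 + lambda * |b|^(1/2) is minimized at exactly zero. For the
#' half-weighted form (1/2)(b - omega)^2 + L * |b|^(1/2) the corresponding
#' boundary is `threshold_boundary(2 * L)` = (3/2) * L^(2/3).
#'
#' @param lambda Penalty weight(s), >= 0.
#' @return Numeric vector of boundary values.
#' @export
threshold_boundary <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  (54^(1 / 3) / 4) * lambda^(2 / 3)
}

#' Coordinate descent for L1/2-penalized (weighted) least squares
#'
#' Minimizes (1/(2n)) * sum_i w_i (y_i - x_i' beta)^2 +
#' lambda * sum_j |beta_j|^(1/2) by cyclic coordinate descent. Each
#' coordinate update solves its scalar subproblem exactly by applying
#' [half_threshold()] at penalty 2 * lambda (see that page's calibration
#' note) to the partial-residual correlation
#' omega_j = (1/n) sum_i w_i x_ij (y_i - ytilde_i^(j)), so the objective is
#' non-increasing sweep to sweep. Columns of `X` should satisfy
#' sum_i x_ij^2 = n (see [standardize_features()]); under weights, the
#' per-coordinate curvature (1/n) sum_i w_i x_ij^2 is accounted for exactly.
#' The order of updates is cyclic, initialization defaults to zero, and after
#' each full sweep the current support is iterated to convergence
#' (active-set cycling). The penalty is nonconvex, so the result is a
#' fixed point of the operator with non-increasing objective, not a
#' certified global minimum; the convention (cyclic order, zero start,
#' warm starts along a path) is fixed for reproducibility.
#'
#' @param X Standardized n x p matrix.
#' @param y Working response (length n).
#' @param lambda Penalty weight >= 0.
#' @param weights Optional positive observation weights (default 1).
#' @param beta_init Optional warm start (default zero).
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   sweep (default 1e-5).
#' @param max_sweeps Sweep cap (default 10000).
#' @return A list with `beta` (named if `X` has column names), `n_iter`,
#'   `converged`, and `objective_trace` (objective after each sweep).
#' @export
coordinate_descent_l12 <- function(X, y, lambda, weights = NULL,
                                   beta_init = NULL, tol = 1e-5,
                                   max_sweeps = 10000) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (tol <= 0) stop("tol must be positive")
  weights <- weights %||% rep(1, n)
  if (any(weights < 0)) stop("weights must be nonnegative")
  beta_init <- beta_init %||% numeric(p)
  res <- cd_l12_cpp(X, as.numeric(y), as.numeric(weights), lambda,
                    as.numeric(beta_init), tol, as.integer(max_sweeps))
  names(res$beta) <- colnames(X)
  res
}

#' Log-spaced penalty path
#'
#' Builds a descending log-spaced grid of `n_lambda` penalties from
#' lambda_max down to `ratio * lambda_max`, where lambda_max is the smallest
#' penalty that zeroes every coordinate at the zero start: inverting the
#' solver's threshold condition |omega_j / v_j| <= (3/2)(lambda / v_j)^(2/3)
#' gives lambda_max = max_j v_j * (2 |omega_j / v_j| / 3)^(3/2), with
#' omega_j = (1/n) sum_i w_i x_ij y_i and curvature
#' v_j = (1/n) sum_i w_i x_ij^2.
#'
#' @param X Standardized n x p matrix.
#' @param y Response (length n).
#' @param n_lambda Grid size (>= 1).
#' @param ratio Smallest/largest penalty ratio in (0, 1).
#' @param weights Optional observation weights.
#' @return Descending numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(X, y, n_lambda = 20, ratio = 0.08, weights = NULL) {
  if (n_lambda < 1) stop("n_lambda must be at least 1")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  X <- as.matrix(X)
  n <- nrow(X)
  weights <- weights %||% rep(1, n)
  omega <- drop(crossprod(X, weights * y)) / n
  v <- drop(crossprod(X^2, weights)) / n
  ok <- v > 0 & abs(omega) > 0
  if (!any(ok)) stop("response is orthogonal to every feature; no path exists")
  # tiny inflation keeps the zero solution on the right side of the
  # activation boundary despite floating-point rounding of the powers
  lam_max <- max(v[ok] * (2 * abs(omega[ok] / v[ok]) / 3)^(3 / 2)) * (1 + 1e-9)
  if (n_lambda == 1) return(lam_max)
  exp(seq(log(lam_max), log(ratio * lam_max), length.out = n_lambda))
}
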