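#' Standardize covariate columns
#'
#' Centers each feature and scales it so the column sum of squares equals the
#' sample size n (population scaling, not the n-1 variance convention). Under
#' this scaling the coordinate-wise update of the L1/2 solver reduces exactly
#' to the scalar problem min_b (1/2)(b - omega_j)^2 + lambda*|b|^(1/2), whose
#' closed-form minimizer is [half_threshold()]. Constant columns carry no
#' information and are dropped with a warning.
#'
#' @param data A survival tibble (see [validate_survival_data()]).
#' @return A list with `data` (the standardized tibble) and `params` (a tibble
#'   with columns `feature`, `center`, `scale` permitting exact
#'   back-transformation of coefficients to the original scale).
#' @export
#' @examples
#' sim <- simulate_survival(n = 30, p = 4, n_informative = 2, seed = 1)
#' std <- standardize_features(sim$data)
#' colMeans(feature_matrix(std$data)) # ~0
standardize_features <- function(data) {
  data <- validate_survival_data(data)
  X <- feature_matrix(data)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(Xc^2))
  keep <- scale > 0
  if (!any(keep)) stop("all feature columns are constant")
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, scale[keep], "/")
  out <- dplyr::bind_cols(data[c("sample_id", "time", "status")],
                          tibble::as_tibble(Xs))
  list(
    data = out,
    params = tibble::tibble(feature = colnames(X)[keep],
                            center = unname(center[keep]),
                            scale = unname(scale[keep]))
  )
}

# Apply stored standardization parameters to a raw feature matrix.
std_apply <- function(X, params) {
  X <- X[, params$feature, drop = FALSE]
  sweep(sweep(X, 2, params$center), 2, params$scale, "/")
}

# Map coefficients fitted on the standardized scale back to the raw scale.
# Returns list(beta, intercept_shift): x_raw' beta + intercept_shift equals
# x_std' beta_std.
std_backtransform <- function(beta_std, params) {
  beta <- beta_std / params$scale
  names(beta) <- params$feature
  list(beta = beta, intercept_shift = -sum(beta * params$center))
}
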