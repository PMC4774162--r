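#' Censoring-weighted Brier score at a time point
#'
#' BS(t) = (1/n) sum_i \[ S(t|X_i)^2 1(t_i <= t, delta_i = 1) / G(t_i-) +
#' (1 - S(t|X_i))^2 1(t_i > t) / G(t-) \], where G is the Kaplan-Meier
#' estimator of the censoring distribution (the product-limit curve of
#' (time, 1 - status)). Weights are evaluated at left limits, the usual
#' inverse-probability-of-censoring convention; samples whose weight
#' denominator is 0 are excluded with n adjusted accordingly.
#'
#' @param data A survival tibble.
#' @param pred Survival predictions: a function `f(times)` returning an
#'   n x length(times) matrix of S(t | X_i), or such a matrix when `t` is
#'   scalar/vector-matching (see [survival_curves()]).
#' @param t Evaluation time (scalar, >= 0).
#' @return The Brier score at `t`.
#' @export
brier_score <- function(data, pred, t) {
  if (t < 0) stop("t must be nonnegative")
  data <- validate_survival_data(data)
  s <- eval_surv_pred(pred, t, nrow(data))
  G <- km_estimator(data$time, 1 - data$status)
  brier_core(data$time, data$status, s, t, G)
}

# Shared IPCW Brier computation against a precomputed censoring curve.
brier_core <- function(time, status, s, t, G) {
  w_event <- km_surv_at(G, time, left = TRUE)
  w_alive <- km_surv_at(G, t, left = TRUE)
  ev <- time <= t & status == 1
  alive <- time > t
  contrib <- numeric(length(time))
  ok <- rep(TRUE, length(time))
  contrib[ev] <- s[ev]^2 / w_event[ev]
  contrib[alive] <- (1 - s[alive])^2 / w_alive
  ok[ev & w_event == 0] <- FALSE
  if (w_alive == 0) ok[alive] <- FALSE
  contrib[ev & w_event == 0] <- 0
  # censored before t contribute 0 with weight 1 (their status at t is unknown)
  sum(contrib[ok]) / sum(ok)
}

eval_surv_pred <- function(pred, t, n) {
  s <- if (is.function(pred)) pred(t) else pred
  s <- drop(as.matrix(s))
  if (length(s) != n) stop("survival predictions must have one value per sample")
  if (any(s < -1e-8 | s > 1 + 1e-8)) stop("survival predictions must lie in [0, 1]")
  pmin(pmax(as.numeric(s), 0), 1)
}

#' Integrated Brier score
#'
#' IBS = (1 / max(t_i)) * integral_0^max(t_i) BS(t) dt. For the step-function
#' predictors used here BS(t) is piecewise constant on the open intervals
#' between consecutive observed times (the left-limit censoring weight means
#' the value exactly at a censoring time differs from the value just past
#' it), so the integral is evaluated exactly as a sum over those intervals,
#' each contributing its midpoint Brier score times its width.
#'
#' @param data A survival tibble.
#' @param pred A function `f(times)` returning an n x length(times) matrix
#'   of survival probabilities (see [survival_curves()]).
#' @return The integrated Brier score; lower is better.
#' @export
integrated_brier <- function(data, pred) {
  data <- validate_survival_data(data)
  grid <- sort(unique(c(0, data$time)))
  tmax <- max(data$time)
  widths <- diff(grid)
  mids <- grid[-length(grid)] + widths / 2
  S <- if (is.function(pred)) pred(mids) else pred
  S <- as.matrix(S)
  if (nrow(S) != nrow(data) || ncol(S) != length(mids)) {
    stop("pred must yield one survival value per sample and interval")
  }
  G <- km_estimator(data$time, 1 - data$status)
  bs <- vapply(seq_along(mids), function(k) {
    brier_core(data$time, data$status,
               pmin(pmax(S[, k], 0), 1), mids[k], G)
  }, numeric(1))
  sum(bs * widths) / tmax
}

#' Survival-curve predictor for a fitted model
#'
#' Wraps a `cox_l12` or `aft_l12` fit and a dataset into the `f(times)`
#' closure consumed by [brier_score()] and [integrated_brier()]: Cox models
#' use the Breslow baseline, AFT models the Kaplan-Meier estimator of their
#' training residuals.
#'
#' @param fit A `cox_l12` or `aft_l12` fit.
#' @param data Samples to predict for.
#' @return A function mapping a vector of times to an n x length(times)
#'   matrix of survival probabilities.
#' @export
survival_curves <- function(fit, data) {
  force(fit)
  force(data)
  function(times) predict(fit, data, type = "survival", times = times)
}

#' Concordance index for censored data
#'
#' The fraction of comparable sample pairs whose predicted ordering agrees
#' with the observed one. A pair (i, j) is comparable when t_i < t_j and
#' delta_i = 1 (the earlier time is an observed event); it is concordant
#' when f_i < f_j, with `pred` oriented so that larger values mean longer
#' predicted survival (negate Cox prognostic scores before calling). Tied
#' predictions are not concordant, and the index is invariant to strictly
#' monotone transforms of `pred`.
#'
#' @param data A survival tibble.
#' @param pred Numeric predictions, larger = longer predicted survival.
#' @return The concordance index in \[0, 1\], or NA (with a warning) when no
#'   pair is comparable.
#' @export
#' @examples
#' d <- tibble::tibble(time = 1:4, status = 1, g1 = 0)
#' concordance_index(d, c(2, 1, 4, 3)) # 4 of 6 pairs concordant
concordance_index <- function(data, pred) {
  data <- validate_survival_data(data)
  if (length(pred) != nrow(data)) stop("pred must have one value per sample")
  t <- data$time
  d <- data$status
  comp <- outer(t, t, "<") & (d == 1)
  n_comp <- sum(comp)
  if (n_comp == 0) {
    warning("no comparable pairs; concordance index undefined")
    return(NA_real_)
  }
  conc <- outer(pred, pred, "<") & comp
  sum(conc) / n_comp
}

#' Gene-selection precision
#'
#' Precision = number of correctly selected features / total selected.
#' An empty selection has undefined precision (NA) and should be excluded
#' from replicate averages.
#'
#' @param selected Character vector (or index set) of selected features.
#' @param true_support The informative features.
#' @return A one-row tibble with `n_correct`, `n_selected`, `precision`.
#' @export
#' @examples
#' selection_precision(c("g1", "g2", "g11"), paste0("g", 1:10))$precision # 2/3
selection_precision <- function(selected, true_support) {
  n_sel <- length(selected)
  n_cor <- length(intersect(selected, true_support))
  tibble::tibble(n_correct = n_cor, n_selected = n_sel,
                 precision = if (n_sel > 0) n_cor / n_sel else NA_real_)
}
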