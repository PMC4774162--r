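#' Kaplan-Meier product-limit estimator
#'
#' Computes the product-limit survival curve: at each distinct observed time
#' the survival estimate multiplies by (1 - d/r) where d is the number of
#' events and r the number at risk; censored observations shrink risk sets
#' but contribute no drop. The per-time drop `step` = S(t-) - S(t) is carried
#' explicitly because the conditional-mean imputation of censored responses
#' weights later event times by exactly these steps.
#'
#' @param time Observed times.
#' @param status Event indicators (1 = event, 0 = censored).
#' @return A `km_curve` tibble with one row per distinct observed time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `step`.
#' @export
#' @examples
#' km_estimator(c(1, 2, 3, 4), c(1, 0, 1, 1))$surv # 0.75 0.75 0.375 0
km_estimator <- function(time, status) {
  if (length(time) != length(status)) stop("time and status lengths differ")
  ut <- sort(unique(time))
  n_event <- vapply(ut, function(u) sum(time == u & status == 1), numeric(1))
  n_cens <- vapply(ut, function(u) sum(time == u & status == 0), numeric(1))
  n_risk <- vapply(ut, function(u) sum(time >= u), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  step <- c(1, surv[-length(surv)]) - surv
  if (!length(ut)) {
    surv <- numeric(0)
    step <- numeric(0)
  }
  out <- tibble::tibble(time = ut, n_risk = as.integer(n_risk),
                        n_event = as.integer(n_event),
                        n_censor = as.integer(n_cens),
                        surv = surv, step = step)
  class(out) <- c("km_curve", class(out))
  attr(out, "n") <- length(time)
  out
}

# Evaluate a km_curve at arbitrary times; left = TRUE gives the left limit
# S(t-), i.e. the value just before any drop at t.
km_surv_at <- function(curve, t, left = FALSE) {
  idx <- findInterval(t, curve$time, left.open = left)
  c(1, curve$surv)[idx + 1]
}

#' Kaplan-Meier conditional-mean imputation of censored responses
#'
#' For each censored sample the response h(t) (h = log by default) is
#' replaced by the estimated conditional mean of h(T) given T > t:
#' h(t*) = S(t)^(-1) * sum_\{t_(r) > t\} h(t_(r)) * dS(t_(r)),
#' where S is the Kaplan-Meier estimator and dS(t_(r)) its drop at event
#' time t_(r); the sum runs over event times strictly greater than the
#' censored time. Event samples pass through unchanged. A censored sample
#' with no later event time has an empty sum; it receives h(largest event
#' time) as the conventional redistribute-to-the-right fallback and is
#' flagged `undefined_tail` so downstream steps can exclude it.
#'
#' @param data A survival tibble.
#' @param h Monotone response transform (default `log`).
#' @return A tibble with `sample_id`, `time`, `status`, `h_star`,
#'   `was_imputed`, and `undefined_tail`.
#' @export
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3, 4), status = c(1, 0, 1, 1), g1 = 0:3)
#' km_mean_impute(d)$h_star[2] # (log(3)*0.375 + log(4)*0.375) / 0.75
km_mean_impute <- function(data, h = log) {
  data <- validate_survival_data(data)
  curve <- km_estimator(data$time, data$status)
  imp <- impute_with_curve(data$time, curve, h)
  ev <- data$status == 1
  tibble::tibble(
    sample_id = data$sample_id,
    time = data$time,
    status = data$status,
    h_star = ifelse(ev, h(data$time), imp$h_star),
    was_imputed = !ev,
    undefined_tail = !ev & imp$undefined_tail
  )
}

# Impute h-scale responses for the given (censored) times against a fitted
# km_curve. Returns h_star and the undefined-tail flag for each time.
impute_with_curve <- function(times, curve, h = log) {
  ev_rows <- curve$n_event > 0
  et <- curve$time[ev_rows]
  steps <- curve$step[ev_rows]
  h_et <- if (length(et)) h(et) else numeric(0)
  n <- length(times)
  h_star <- numeric(n)
  undef <- logical(n)
  for (i in seq_len(n)) {
    later <- et > times[i]
    if (!any(later)) {
      undef[i] <- TRUE
      h_star[i] <- if (length(et)) h(max(et)) else h(times[i])
    } else {
      denom <- km_surv_at(curve, times[i])
      h_star[i] <- sum(h_et[later] * steps[later]) / denom
    }
  }
  list(h_star = h_star, undefined_tail = undef)
}

#' Cross-validated penalty tuning for the L1/2 AFT model
#'
#' Selects the penalty minimizing the held-out mean squared error on the
#' h-scale. Only held-out samples flagged eligible contribute to the loss:
#' by default observed events, so that predictions are never scored against
#' fabricated (imputed) targets. Ties go to the larger, sparser penalty.
#'
#' @param data A survival tibble (supplies covariates and fold strata).
#' @param h_star Response vector on the h-scale (observed or imputed).
#' @param lambdas Optional descending penalty grid.
#' @param folds Optional fold tibble from [stratified_kfold()].
#' @param nfolds,seed Fold construction when `folds` is NULL.
#' @param cv_eligible Logical vector marking responses trusted in the
#'   held-out loss (default: `data$status == 1`).
#' @param n_lambda,lambda_min_ratio Grid size/span when `lambdas` is NULL.
#' @return A list with `lambda`, `cv_table` (lambda, mse, n_selected on the
#'   full-data path), and `folds`.
#' @export
cv_tune_aft <- function(data, h_star, lambdas = NULL, folds = NULL,
                        nfolds = 5, seed = 1, cv_eligible = NULL,
                        n_lambda = 20, lambda_min_ratio = 0.08) {
  data <- validate_survival_data(data)
  if (any(!is.finite(h_star))) stop("h_star must be finite")
  cv_eligible <- cv_eligible %||% (data$status == 1)
  if (!any(cv_eligible)) stop("no samples eligible for the held-out loss")
  std <- standardize_features(data)
  Xs <- feature_matrix(std$data)
  yc <- h_star - mean(h_star)
  if (is.null(lambdas)) {
    lambdas <- lambda_path(Xs, yc, n_lambda = n_lambda, ratio = lambda_min_ratio)
  }
  folds <- folds %||% stratified_kfold(data, k = nfolds, seed = seed)
  k <- attr(folds, "k") %||% max(folds$fold)
  X_raw <- feature_matrix(data)
  se <- numeric(length(lambdas))
  cnt <- 0
  for (f in seq_len(k)) {
    hold <- folds$fold == f
    use <- hold & cv_eligible
    if (!any(use)) next
    train <- data[!hold, , drop = FALSE]
    std_tr <- standardize_features(train)
    Xs_tr <- feature_matrix(std_tr$data)
    y_tr <- h_star[!hold]
    path <- aft_path_std(Xs_tr, y_tr - mean(y_tr), lambdas)
    for (l in seq_along(lambdas)) {
      bt <- std_backtransform(path[, l], std_tr$params)
      b0 <- mean(y_tr) + bt$intercept_shift
      pred <- b0 + drop(X_raw[use, std_tr$params$feature, drop = FALSE] %*% bt$beta)
      se[l] <- se[l] + sum((h_star[use] - pred)^2)
    }
    cnt <- cnt + sum(use)
  }
  mse <- se / cnt
  best <- which(mse <= min(mse) + 1e-12)[1] # grid descends: first = largest lambda
  full_path <- aft_path_std(Xs, yc, lambdas)
  list(lambda = lambdas[best],
       cv_table = tibble::tibble(lambda = lambdas, mse = mse,
                                 n_selected = colSums(full_path != 0)),
       folds = folds)
}

aft_path_std <- function(Xs, yc, lambdas, tol = 1e-5, max_sweeps = 2000) {
  beta <- numeric(ncol(Xs))
  out <- matrix(0, ncol(Xs), length(lambdas),
                dimnames = list(colnames(Xs), NULL))
  for (l in seq_along(lambdas)) {
    beta <- cd_l12_cpp(Xs, yc, rep(1, nrow(Xs)), lambdas[l], beta, tol,
                       as.integer(max_sweeps))$beta
    out[, l] <- beta
  }
  out
}

#' Fit an L1/2-penalized accelerated failure time model
#'
#' Linear model h(t_i) = beta_0 + x_i' beta + eps_i for the log survival
#' time, fitted by penalized least squares with the L1/2 penalty. Censored
#' responses must first be replaced by imputed values; when `h_star` is not
#' supplied it is computed by global [km_mean_impute()]. Features are
#' standardized and the response centered internally (the intercept is the
#' response mean on the centered-feature scale); coefficients are reported
#' on the original scale.
#'
#' @param data A survival tibble.
#' @param h_star Optional response vector on the h-scale; defaults to the
#'   Kaplan-Meier conditional-mean imputation of `data`.
#' @param lambda `"cv"` (default) or a fixed nonnegative penalty.
#' @param nfolds,seed Cross-validation controls.
#' @param cv_eligible Logical mask for the held-out CV loss (default:
#'   observed events).
#' @param n_lambda,lambda_min_ratio Penalty-grid controls.
#' @param h Monotone transform used when imputing (default `log`).
#' @return An object of class `aft_l12`: `intercept`, `beta` (original
#'   scale), `selected`, `lambda`, `standardization`, `cv` table or NULL,
#'   `h_star`, and `residual_km` ingredients for survival-probability
#'   prediction.
#' @seealso [predict_log_time()], [cv_tune_aft()]
#' @export
#' @examples
#' sim <- simulate_survival(n = 60, p = 8, n_informative = 2, seed = 4)
#' fit <- fit_aft_l12(sim$data, lambda = 0.1)
#' glance(fit)
fit_aft_l12 <- function(data, h_star = NULL, lambda = "cv", nfolds = 5,
                        seed = 1, cv_eligible = NULL, n_lambda = 20,
                        lambda_min_ratio = 0.08, h = log) {
  data <- validate_survival_data(data)
  if (is.null(h_star)) {
    imp <- km_mean_impute(data, h)
    h_star <- imp$h_star
  }
  if (any(!is.finite(h_star))) stop("h_star must be finite")
  std <- standardize_features(data)
  Xs <- feature_matrix(std$data)
  yc <- h_star - mean(h_star)
  cv <- NULL
  if (identical(lambda, "cv")) {
    cv <- cv_tune_aft(data, h_star, nfolds = nfolds, seed = seed,
                      cv_eligible = cv_eligible, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio)
    lambdas <- cv$cv_table$lambda
    lambdas <- lambdas[lambdas >= cv$lambda - 1e-12]
    lambda <- cv$lambda
  } else {
    if (!is.numeric(lambda) || lambda < 0) stop("lambda must be 'cv' or a nonnegative number")
    grid <- tryCatch(lambda_path(Xs, yc, n_lambda, lambda_min_ratio),
                     error = function(e) numeric(0))
    lambdas <- c(grid[grid > lambda], lambda)
  }
  beta_std <- aft_path_std(Xs, yc, lambdas)[, length(lambdas)]
  bt <- std_backtransform(beta_std, std$params)
  intercept <- mean(h_star) + bt$intercept_shift
  pred <- intercept + drop(feature_matrix(data)[, std$params$feature, drop = FALSE] %*% bt$beta)
  structure(list(
    intercept = intercept,
    beta = bt$beta,
    lambda = lambda,
    selected = names(bt$beta)[bt$beta != 0],
    standardization = std$params,
    cv = if (is.null(cv)) NULL else cv$cv_table,
    h_star = h_star,
    residual_km = list(resid = h(data$time) - pred, status = data$status),
    nobs = nrow(data)
  ), class = "aft_l12")
}

#' Predicted log survival time from an AFT fit
#'
#' @param fit An `aft_l12` fit.
#' @param data A tibble containing the fit's feature columns.
#' @return beta_0 + x' beta on the h (log-time) scale; exponentiate for the
#'   time scale.
#' @export
predict_log_time <- function(fit, data) {
  feats <- fit$standardization$feature
  missing <- setdiff(feats, names(data))
  if (length(missing)) stop("data lacks feature(s): ", paste(head(missing, 5), collapse = ", "))
  fit$intercept + drop(as.matrix(data[feats]) %*% fit$beta[feats])
}

#' Predict from an L1/2 AFT fit
#'
#' @param object An `aft_l12` fit.
#' @param newdata A tibble with the fit's feature columns.
#' @param type `"lp"` for the log-time scale, `"time"` for exp(lp), or
#'   `"survival"` for a matrix of S(t | x) over `times` obtained by applying
#'   the Kaplan-Meier estimator of the training residuals to t's residual.
#' @param times Evaluation times for `type = "survival"`.
#' @param ... Unused.
#' @export
predict.aft_l12 <- function(object, newdata, type = c("lp", "time", "survival"),
                            times = NULL, ...) {
  type <- match.arg(type)
  lp <- predict_log_time(object, newdata)
  if (type == "lp") return(lp)
  if (type == "time") return(exp(lp))
  if (is.null(times)) stop("type = 'survival' requires times")
  rk <- km_estimator(object$residual_km$resid, object$residual_km$status)
  out <- matrix(0, length(lp), length(times))
  for (j in seq_along(times)) {
    out[, j] <- km_surv_at(rk, log(times[j]) - lp)
  }
  out
}

#' @export
print.aft_l12 <- function(x, ...) {
  cat("L1/2-penalized AFT model: ", length(x$selected), " of ",
      length(x$beta), " features selected (lambda = ", signif(x$lambda, 4),
      ")\n", sep = "")
  cat("intercept =", round(x$intercept, 4), "on the log-time scale; n =",
      x$nobs, "\n")
  invisible(x)
}
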