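# Precomputed risk-set structure for a fixed (time, status): everything the
# partial-likelihood quantities need that does not depend on eta. Event-time
# risk sets are indexed once so IRLS iterations stay O(n) vector work.
cox_setup <- function(time, status) {
  ord <- order(time)
  t_s <- time[ord]
  d_s <- status[ord]
  ev <- d_s == 1
  ut <- unique(t_s[ev]) # ascending distinct event times
  first <- match(ut, t_s) # first sorted index with t_j >= t_(r)
  d_r <- as.numeric(tabulate(match(t_s[ev], ut), nbins = length(ut)))
  list(n = length(time), ord = ord, t_s = t_s, ev_sorted = ev,
       events = status == 1, ut = ut, first = first, d_r = d_r,
       idx = findInterval(time, ut)) # events at times <= t_i, per sample
}

# Unscaled Breslow log partial likelihood at linear predictor eta.
cox_pl_setup <- function(eta, setup) {
  if (!length(setup$ut)) return(0)
  m <- max(eta)
  ex <- exp(eta[setup$ord] - m)
  rs <- rev(cumsum(rev(ex))) # sum_{j: t_j >= t_s[i]} exp(eta_j - m)
  sum(eta[setup$events]) - sum(setup$d_r * (log(rs[setup$first]) + m))
}

cox_pl_unscaled <- function(eta, time, status) {
  cox_pl_setup(eta, cox_setup(time, status))
}

# Per-sample gradient and diagonal Hessian of the unscaled negative log
# partial likelihood with respect to eta, plus the IRLS working response.
cox_working_setup <- function(eta, setup, w_floor = 1e-5) {
  m <- max(eta)
  ex_s <- exp(eta[setup$ord] - m)
  rs <- rev(cumsum(rev(ex_s)))
  S_r <- rs[setup$first]
  cumA <- cumsum(setup$d_r / S_r)
  cumB <- cumsum(setup$d_r / S_r^2)
  A <- c(0, cumA)[setup$idx + 1]
  B <- c(0, cumB)[setup$idx + 1]
  ex <- exp(eta - m)
  g <- as.numeric(setup$events) - ex * A
  w <- pmax(ex * A - ex^2 * B, w_floor)
  list(g = g, w = w, z = eta + g / w)
}

cox_working <- function(eta, time, status, w_floor = 1e-5) {
  cox_working_setup(eta, cox_setup(time, status), w_floor)
}

#' Cox log partial likelihood
#'
#' Evaluates the (1/n)-scaled Breslow log partial likelihood
#' l(beta) = (1/n) sum_\{r in D\} \[beta' x_(r) - log sum_\{j in R_r\}
#' exp(beta' x_j)\], where D indexes observed events and R_r is the risk set
#' at the r-th ordered event time. Tied event times are handled by the
#' Breslow convention. The computation subtracts the maximum linear
#' predictor before exponentiating to avoid overflow.
#'
#' @param data A survival tibble.
#' @param beta Coefficient vector: either named (matched to feature columns)
#'   or of length equal to the number of features.
#' @return The scaled log partial likelihood (0 when no events).
#' @export
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), status = 1, g1 = c(0.5, -1, 0.2))
#' cox_partial_loglik(d, c(g1 = 0)) # (1/3)(log(1/3) + log(1/2)) = -0.5973
cox_partial_loglik <- function(data, beta) {
  data <- validate_survival_data(data)
  X <- feature_matrix(data)
  beta <- match_beta(beta, colnames(X))
  eta <- drop(X %*% beta)
  if (!is.finite(sum(eta))) stop("non-finite linear predictor")
  cox_pl_unscaled(eta, data$time, data$status) / nrow(data)
}

match_beta <- function(beta, feats) {
  if (!is.null(names(beta))) {
    full <- setNames(numeric(length(feats)), feats)
    unknown <- setdiff(names(beta), feats)
    if (length(unknown)) stop("unknown feature(s) in beta: ", paste(unknown, collapse = ", "))
    full[names(beta)] <- beta
    full
  } else {
    if (length(beta) != length(feats)) stop("beta must have length ", length(feats))
    setNames(as.numeric(beta), feats)
  }
}

# Penalized Cox fit on an already-standardized design, by IRLS around the
# partial likelihood with the diagonal-Hessian working response, each
# quadratic subproblem solved by L1/2 coordinate descent. A step-halving
# safeguard keeps the penalized objective non-increasing (the nonconvex
# penalty can make the raw update overshoot).
fit_cox_std <- function(Xs, time, status, lambda, beta_init = NULL,
                        maxit = 100, tol = 1e-4, cd_tol = 1e-5,
                        cd_sweeps = 2000, setup = NULL) {
  n <- nrow(Xs)
  setup <- setup %||% cox_setup(time, status)
  beta <- beta_init %||% numeric(ncol(Xs))
  eta <- drop(Xs %*% beta)
  pen_obj <- function(beta, eta) {
    -cox_pl_setup(eta, setup) / n + lambda * sum(sqrt(abs(beta)))
  }
  f_old <- pen_obj(beta, eta)
  it <- 0
  act <- which(beta != 0)
  # IRLS iterations sweep only the active coordinates (cheap); a full-p
  # sweep runs at the start and again at convergence to let new coordinates
  # enter, until a full pass confirms the fixed point (glmnet-style).
  restricted <- length(act) > 0
  repeat {
    it <- it + 1
    wk <- cox_working_setup(eta, setup)
    if (restricted) {
      sol <- cd_l12_cpp(Xs[, act, drop = FALSE], wk$z, wk$w, lambda,
                        beta[act], cd_tol, as.integer(cd_sweeps))
      bn <- numeric(length(beta))
      bn[act] <- sol$beta
    } else {
      sol <- cd_l12_cpp(Xs, wk$z, wk$w, lambda, beta, cd_tol,
                        as.integer(cd_sweeps))
      bn <- sol$beta
    }
    etan <- wk$z - sol$residual # = Xs %*% bn, maintained by the solver
    halved <- 0
    repeat {
      f_new <- pen_obj(bn, etan)
      if (!is.finite(f_new)) {
        stop("non-finite penalized Cox objective at outer iteration ", it,
             " (lambda = ", signif(lambda, 4), ")")
      }
      if (f_new <= f_old + 1e-10 || halved >= 8) break
      bn <- (bn + beta) / 2
      etan <- drop(Xs %*% bn)
      halved <- halved + 1
    }
    if (f_new > f_old + 1e-10) {
      # The sqrt penalty is not locally Lipschitz at zero, so a shortened
      # step toward a newly activated coordinate can only increase the
      # objective; when even halving fails, the quadratic working model
      # offers no descent from here — keep the current iterate and stop.
      break
    }
    delta <- max(abs(etan - eta))
    beta <- bn
    eta <- etan
    f_old <- f_new
    act <- which(beta != 0)
    if (it >= maxit) break
    if (delta < tol) {
      if (!restricted) break # converged and verified on a full sweep
      restricted <- FALSE # converged on the active set: verify with full p
    } else {
      restricted <- length(act) > 0
    }
  }
  list(beta = beta, eta = eta, n_outer = it, objective = f_old)
}

# Warm-started path of standardized Cox fits over a descending lambda grid.
cox_path_std <- function(Xs, time, status, lambdas, ...) {
  setup <- cox_setup(time, status)
  beta <- numeric(ncol(Xs))
  out <- matrix(0, ncol(Xs), length(lambdas),
                dimnames = list(colnames(Xs), NULL))
  for (l in seq_along(lambdas)) {
    fit <- fit_cox_std(Xs, time, status, lambdas[l], beta_init = beta,
                       setup = setup, ...)
    beta <- fit$beta
    out[, l] <- beta
  }
  out
}

cox_lambda_grid <- function(Xs, time, status, n_lambda, ratio) {
  wk <- cox_working(numeric(nrow(Xs)), time, status)
  lambda_path(Xs, wk$z, n_lambda = n_lambda, ratio = ratio, weights = wk$w)
}

#' Cross-validated penalty tuning for the L1/2 Cox model
#'
#' Selects the penalty by the cross-validated partial likelihood of Verweij
#' and van Houwelingen: for each fold k and each lambda on the grid, the model
#' is fitted on the data without fold k and scored by
#' l_full(beta_(-k)) - l_(-k)(beta_(-k)), the partial-likelihood contribution
#' of the held-out fold; contributions are summed over folds and the lambda
#' maximizing the sum wins (ties go to the larger, sparser lambda). Folds are
#' stratified on the event indicator.
#'
#' @param data A survival tibble.
#' @param lambdas Optional descending penalty grid; defaults to
#'   [lambda_path()] applied to the null-model working response.
#' @param folds Optional fold tibble from [stratified_kfold()].
#' @param nfolds,seed Fold count and seed used when `folds` is NULL.
#' @param n_lambda,lambda_min_ratio Grid size and span when `lambdas` is NULL.
#' @return A list with `lambda` (the selected penalty), `cv_table` (tibble of
#'   lambda, cvpl, and support size on the full-data path), and `folds`.
#' @export
cv_tune_cox <- function(data, lambdas = NULL, folds = NULL, nfolds = 5,
                        seed = 1, n_lambda = 20, lambda_min_ratio = 0.08) {
  data <- validate_survival_data(data)
  if (!any(data$status == 1)) stop("cannot tune a Cox model with no events")
  std <- standardize_features(data)
  Xs <- feature_matrix(std$data)
  if (is.null(lambdas)) {
    lambdas <- cox_lambda_grid(Xs, data$time, data$status, n_lambda, lambda_min_ratio)
  }
  folds <- folds %||% stratified_kfold(data, k = nfolds, seed = seed)
  k <- attr(folds, "k") %||% max(folds$fold)
  X_raw <- feature_matrix(data)
  setup_all <- cox_setup(data$time, data$status)
  cvpl <- numeric(length(lambdas))
  for (f in seq_len(k)) {
    hold <- folds$fold == f
    train <- data[!hold, , drop = FALSE]
    if (!any(train$status == 1)) stop("training fold ", f, " has no events")
    std_tr <- standardize_features(train)
    Xs_tr <- feature_matrix(std_tr$data)
    setup_tr <- cox_setup(train$time, train$status)
    # cap the working-response refits during tuning: penalties deep in the
    # overfit region converge slowly and are never competitive under CVPL
    path <- cox_path_std(Xs_tr, train$time, train$status, lambdas, maxit = 25)
    scales <- std_tr$params$scale
    eta_all_mat <- X_raw[, std_tr$params$feature, drop = FALSE] %*% (path / scales)
    for (l in seq_along(lambdas)) {
      eta_all <- eta_all_mat[, l]
      l_all <- cox_pl_setup(eta_all, setup_all)
      l_tr <- cox_pl_setup(eta_all[!hold], setup_tr)
      cvpl[l] <- cvpl[l] + (l_all - l_tr)
    }
  }
  best <- which(cvpl >= max(cvpl) - 1e-9)[1] # grid descends: first = largest lambda
  full_path <- cox_path_std(Xs, data$time, data$status, lambdas, maxit = 25)
  list(lambda = lambdas[best],
       cv_table = tibble::tibble(lambda = lambdas, cvpl = cvpl,
                                 n_selected = colSums(full_path != 0)),
       folds = folds)
}

#' Fit an L1/2-penalized Cox proportional hazards model
#'
#' Minimizes the negative Breslow log partial likelihood (scaled by 1/n) plus
#' lambda * sum_j |beta_j|^(1/2). The outer loop forms a quadratic working
#' problem from the gradient and diagonal Hessian of the partial likelihood
#' at the current linear predictor; the inner loop solves it with
#' [coordinate_descent_l12()]. Features are standardized internally and
#' coefficients reported on the original scale. With `lambda = "cv"` the
#' penalty is tuned by [cv_tune_cox()] and the final model is refit on the
#' full data along the warm-started path down to the selected penalty.
#'
#' @param data A survival tibble with at least one event.
#' @param lambda `"cv"` (default) or a fixed nonnegative penalty.
#' @param nfolds,seed Cross-validation folds and seed (used when tuning).
#' @param n_lambda,lambda_min_ratio Penalty-grid size and span.
#' @param maxit,tol Outer IRLS iteration cap and tolerance on the maximum
#'   change in the linear predictor.
#' @return An object of class `cox_l12`: coefficients `beta` (original
#'   scale), `selected` feature names, `lambda`, `baseline` (Breslow
#'   cumulative-hazard step function as a tibble), `standardization` params,
#'   `train_scores` (training prognostic indices), `cv` table or NULL,
#'   `loglik` ((1/n)-scaled), `nobs` and `nevents`.
#' @seealso [classify_risk()], [breslow_baseline()], [predict.cox_l12()]
#' @export
#' @examples
#' sim <- simulate_survival(n = 60, p = 8, n_informative = 2, seed = 3)
#' fit <- fit_cox_l12(sim$data, lambda = 0.05)
#' tidy(fit)
fit_cox_l12 <- function(data, lambda = "cv", nfolds = 5, seed = 1,
                        n_lambda = 20, lambda_min_ratio = 0.08,
                        maxit = 100, tol = 1e-4) {
  data <- validate_survival_data(data)
  if (!any(data$status == 1)) stop("cannot fit a Cox model with no events")
  std <- standardize_features(data)
  Xs <- feature_matrix(std$data)
  cv <- NULL
  if (identical(lambda, "cv")) {
    cv <- cv_tune_cox(data, nfolds = nfolds, seed = seed,
                      n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio)
    lambdas <- cv$cv_table$lambda
    lambdas <- lambdas[lambdas >= cv$lambda - 1e-12]
    beta_std <- cox_path_std(Xs, data$time, data$status, lambdas,
                             maxit = maxit, tol = tol)[, length(lambdas)]
    lambda <- cv$lambda
  } else {
    if (!is.numeric(lambda) || lambda < 0) stop("lambda must be 'cv' or a nonnegative number")
    grid <- tryCatch(
      cox_lambda_grid(Xs, data$time, data$status, n_lambda, lambda_min_ratio),
      error = function(e) numeric(0))
    lambdas <- c(grid[grid > lambda], lambda)
    beta_std <- cox_path_std(Xs, data$time, data$status, lambdas,
                             maxit = maxit, tol = tol)[, length(lambdas)]
  }
  bt <- std_backtransform(beta_std, std$params)
  eta <- drop(feature_matrix(data)[, std$params$feature, drop = FALSE] %*% bt$beta)
  fit <- structure(list(
    beta = bt$beta,
    lambda = lambda,
    selected = names(bt$beta)[bt$beta != 0],
    standardization = std$params,
    train_scores = setNames(eta, data$sample_id),
    cv = if (is.null(cv)) NULL else cv$cv_table,
    loglik = cox_pl_unscaled(eta, data$time, data$status) / nrow(data),
    nobs = nrow(data),
    nevents = sum(data$status == 1)
  ), class = "cox_l12")
  fit$baseline <- breslow_baseline(fit, data)
  fit
}

#' Breslow baseline cumulative hazard
#'
#' Computes H0(t) = sum_\{t_(r) <= t\} d_r / sum_\{j in R_r\} exp(beta' x_j)
#' at each distinct event time; the implied survival function is
#' S(t | x) = exp(-H0(t) * exp(beta' x)). With beta = 0 and no censoring this
#' collapses to the Nelson-Aalen estimator.
#'
#' @param fit A `cox_l12` fit.
#' @param data The survival tibble to estimate the baseline on (normally the
#'   training data).
#' @return A tibble with columns `time` (distinct event times, ascending),
#'   `n_event`, and `cumhaz` (non-decreasing, starting from the first event).
#' @export
breslow_baseline <- function(fit, data) {
  data <- validate_survival_data(data)
  eta <- predict(fit, data, type = "lp")
  m <- max(eta)
  ord <- order(data$time)
  t_s <- data$time[ord]
  d_s <- data$status[ord]
  ex_s <- exp(eta[ord] - m)
  rs <- rev(cumsum(rev(ex_s)))
  ev <- d_s == 1
  ut <- unique(t_s[ev])
  if (!length(ut)) {
    return(tibble::tibble(time = numeric(0), n_event = integer(0), cumhaz = numeric(0)))
  }
  first <- match(ut, t_s)
  d_r <- vapply(ut, function(u) sum(t_s == u & ev), numeric(1))
  tibble::tibble(time = ut, n_event = as.integer(d_r),
                 cumhaz = cumsum(d_r / rs[first]) * exp(-m))
}

#' Predict from an L1/2 Cox fit
#'
#' @param object A `cox_l12` fit.
#' @param newdata A survival tibble (or any tibble with the fit's feature
#'   columns).
#' @param type `"lp"` for the prognostic index beta' x, `"risk"` for
#'   exp(beta' x), or `"survival"` for a matrix of S(t | x) over `times`
#'   based on the stored Breslow baseline.
#' @param times Evaluation times (required for `type = "survival"`).
#' @param ... Unused.
#' @return A numeric vector, or an n x length(times) matrix for
#'   `type = "survival"`.
#' @export
predict.cox_l12 <- function(object, newdata, type = c("lp", "risk", "survival"),
                            times = NULL, ...) {
  type <- match.arg(type)
  feats <- object$standardization$feature
  missing <- setdiff(feats, names(newdata))
  if (length(missing)) stop("newdata lacks feature(s): ", paste(head(missing, 5), collapse = ", "))
  X <- as.matrix(newdata[feats])
  eta <- drop(X %*% object$beta[feats])
  if (type == "lp") return(eta)
  if (type == "risk") return(exp(eta))
  if (is.null(times)) stop("type = 'survival' requires times")
  bl <- object$baseline
  idx <- findInterval(times, bl$time)
  H0 <- c(0, bl$cumhaz)[idx + 1]
  outer(exp(eta), H0, function(r, h) exp(-h * r))
}

#' Classify samples into low- and high-risk classes
#'
#' Scores every sample by the prognostic index beta' x and labels it `high`
#' when the score strictly exceeds the threshold, else `low`. The default
#' threshold is the median prognostic index of the samples the model was
#' trained on, which guarantees non-degenerate classes on the training set;
#' `"zero"` thresholds at 0.
#'
#' @param fit A `cox_l12` fit.
#' @param data Survival tibble of samples to classify (may include samples
#'   not used for training, e.g. censored ones).
#' @param threshold_rule `"median"` (of the training scores) or `"zero"`.
#' @param threshold Optional explicit numeric threshold overriding the rule.
#' @return A `risk_partition` tibble with columns `sample_id`, `score`,
#'   `risk` (factor low/high) and attribute `threshold`.
#' @export
classify_risk <- function(fit, data, threshold_rule = c("median", "zero"),
                          threshold = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  data <- validate_survival_data(data)
  if (!length(fit$selected)) {
    stop("all coefficients are zero, so every prognostic score is equal; ",
         "refit with a smaller lambda before risk classification")
  }
  scores <- predict(fit, data, type = "lp")
  thr <- threshold %||% switch(threshold_rule,
                               median = median(fit$train_scores),
                               zero = 0)
  out <- tibble::tibble(sample_id = data$sample_id, score = scores,
                        risk = factor(ifelse(scores > thr, "high", "low"),
                                      levels = c("low", "high")))
  class(out) <- c("risk_partition", class(out))
  attr(out, "threshold") <- thr
  attr(out, "rule") <- threshold_rule
  out
}

#' @export
print.cox_l12 <- function(x, ...) {
  cat("L1/2-penalized Cox model: ", length(x$selected), " of ",
      length(x$beta), " features selected (lambda = ", signif(x$lambda, 4),
      ")\n", sep = "")
  cat("n =", x$nobs, "samples,", x$nevents, "events; scaled log partial",
      "likelihood =", round(x$loglik, 4), "\n")
  invisible(x)
}
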