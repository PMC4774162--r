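#' Validate imputed survival times against censoring times
#'
#' An imputed survival time is usable for training only when it strictly
#' exceeds the observed censored time: censoring already guarantees T > t,
#' so an imputation at or below t contradicts the data and is regarded as an
#' error estimation, to be excluded from model training.
#'
#' @param imputed_time Model-estimated survival times.
#' @param censored_time The corresponding observed censoring times.
#' @return Logical vector: TRUE where the imputation is usable.
#' @export
#' @examples
#' validate_imputations(c(5, 7, 6), c(6, 6, 6)) # FALSE TRUE FALSE
validate_imputations <- function(imputed_time, censored_time) {
  if (length(imputed_time) != length(censored_time)) {
    stop("imputed_time and censored_time lengths differ")
  }
  imputed_time > censored_time
}

# Cox CV fit that falls back to the sparsest penalty with a nonempty support
# when the CV-selected penalty zeroes every coefficient (risk classification
# needs at least one active feature). Returns NULL if no penalty on the grid
# selects anything.
cox_fit_active <- function(data, nfolds, seed, n_lambda, lambda_min_ratio) {
  fit <- fit_cox_l12(data, lambda = "cv", nfolds = nfolds, seed = seed,
                     n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio)
  if (!length(fit$selected) && !is.null(fit$cv)) {
    cand <- fit$cv$lambda[fit$cv$n_selected > 0]
    if (length(cand)) {
      fit <- fit_cox_l12(data, lambda = max(cand), nfolds = nfolds,
                         seed = seed, n_lambda = n_lambda,
                         lambda_min_ratio = lambda_min_ratio)
    }
  }
  if (!length(fit$selected)) NULL else fit
}

#' Run the semi-supervised Cox/AFT learning loop
#'
#' Iterates the workflow that converts censored samples into usable training
#' data. Each iteration: (1) tune and fit the L1/2 Cox model on the current
#' training set (originally complete samples plus previously validated
#' imputed samples, the latter entering as events at their imputed times);
#' (2) score and classify ALL samples into low/high-risk classes;
#' (3) within each risk class, impute the class's censored samples by the
#' Kaplan-Meier conditional mean computed from that class's training
#' samples; (4) tune and fit the L1/2 AFT model on the training set plus the
#' class-imputed censored samples (the class imputations are the warm-start
#' responses; only trusted responses enter the held-out CV loss), then
#' re-predict every censored sample's survival time from the AFT model;
#' (5) keep the censored samples whose AFT-re-estimated time strictly
#' exceeds their censoring time ([validate_imputations()]) — these join the
#' training set as events at the re-estimated times; (6) stop when the
#' validated set is unchanged between iterations or `max_iters` is reached.
#' Final Cox and AFT models are refit on the terminal augmented set.
#'
#' @param data A survival tibble with at least one event.
#' @param max_iters Iteration cap (default 5).
#' @param nfolds Cross-validation folds for both models.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param threshold_rule Risk threshold rule for [classify_risk()].
#' @param n_lambda,lambda_min_ratio Penalty-grid controls.
#' @param restrict_aft_to_cox If TRUE the AFT design matrix is restricted to
#'   the genes selected by the current Cox fit; by default both models see
#'   all features and select independently.
#' @param h Monotone response transform for the AFT model (default `log`).
#' @param verbose Print per-iteration progress.
#' @return An object of class `semisup_result`: final `cox_fit` and
#'   `aft_fit`, the all-sample risk `partition`, the `augmented` training
#'   tibble (complete plus validated imputed samples as events),
#'   `validated` (sample_id, censored_time, imputed_time), `excluded_ids`
#'   (censored samples never validated), a per-`iterations` log tibble, and
#'   `converged`.
#' @export
run_semisupervised <- function(data, max_iters = 5, nfolds = 5, seed = 1,
                               threshold_rule = c("median", "zero"),
                               n_lambda = 20, lambda_min_ratio = 0.08,
                               restrict_aft_to_cox = FALSE, h = log,
                               verbose = FALSE) {
  threshold_rule <- match.arg(threshold_rule)
  data <- validate_survival_data(data)
  if (max_iters < 1) stop("max_iters must be at least 1")
  if (!any(data$status == 1)) stop("no complete samples; cannot start the loop")
  complete <- data[data$status == 1, , drop = FALSE]
  censored <- data[data$status == 0, , drop = FALSE]
  validated <- tibble::tibble(sample_id = character(0),
                              censored_time = numeric(0),
                              imputed_time = numeric(0))
  logs <- list()
  converged <- FALSE
  cox_fit <- NULL
  partition <- NULL

  for (iter in seq_len(max_iters)) {
    train <- augment_training(complete, censored, validated)
    cox_fit <- cox_fit_active(train, nfolds, seed + iter, n_lambda, lambda_min_ratio)
    if (is.null(cox_fit)) {
      warning("no penalty on the grid selects any feature at iteration ",
              iter, "; stopping with the current validated set")
      break
    }
    partition <- classify_risk(cox_fit, data, threshold_rule = threshold_rule)

    if (nrow(censored) == 0) {
      aft_fit_iter <- NULL
      logs[[iter]] <- iteration_log(iter, train, validated, censored, cox_fit, NULL, 0L)
      converged <- TRUE
      break
    }

    # (3) class-wise Kaplan-Meier conditional-mean imputation of the
    # censored samples not already in the training set (validated samples
    # are in `train` at their previously re-estimated times)
    lab <- setNames(as.character(partition$risk), partition$sample_id)
    train_lab <- lab[train$sample_id]
    cens_lab <- lab[censored$sample_id]
    pending <- !(censored$sample_id %in% train$sample_id)
    eq3 <- rep(NA_real_, nrow(censored))
    for (cl in c("low", "high")) {
      in_cl <- which(cens_lab == cl & pending)
      if (!length(in_cl)) next
      cl_train <- train[train_lab == cl, , drop = FALSE]
      if (!nrow(cl_train)) next # empty class: carried over unimputed this round
      curve <- km_estimator(cl_train$time, cl_train$status)
      imp <- impute_with_curve(censored$time[in_cl], curve, h)
      eq3[in_cl][!imp$undefined_tail] <- imp$h_star[!imp$undefined_tail]
    }

    # (4) AFT on training set + class-imputed censored samples
    has_eq3 <- !is.na(eq3)
    aft_data <- dplyr::bind_rows(train, censored[has_eq3, , drop = FALSE])
    if (restrict_aft_to_cox) {
      aft_data <- aft_data[c("sample_id", "time", "status", cox_fit$selected)]
    }
    h_resp <- c(h(train$time), eq3[has_eq3])
    trusted <- c(rep(TRUE, nrow(train)), rep(FALSE, sum(has_eq3)))
    aft_fit_iter <- fit_aft_l12(aft_data, h_star = h_resp, lambda = "cv",
                                nfolds = nfolds, seed = seed + 1000 + iter,
                                cv_eligible = trusted, n_lambda = n_lambda,
                                lambda_min_ratio = lambda_min_ratio, h = h)
    pred_time <- exp(predict_log_time(aft_fit_iter, censored))

    # (5) keep strictly time-consistent re-estimations
    usable <- validate_imputations(pred_time, censored$time)
    validated_new <- tibble::tibble(sample_id = censored$sample_id[usable],
                                    censored_time = censored$time[usable],
                                    imputed_time = pred_time[usable])
    logs[[iter]] <- iteration_log(iter, train, validated_new, censored,
                                  cox_fit, aft_fit_iter, sum(!usable))
    if (verbose) {
      message("iteration ", iter, ": ", nrow(train), " training samples, ",
              sum(usable), "/", nrow(censored), " censored validated")
    }
    same <- setequal(validated_new$sample_id, validated$sample_id)
    validated <- validated_new
    if (same) {
      converged <- TRUE
      break
    }
  }

  augmented <- augment_training(complete, censored, validated)
  # terminal refits on the augmented set
  cox_final <- cox_fit_active(augmented, nfolds, seed, n_lambda, lambda_min_ratio)
  if (is.null(cox_final)) cox_final <- cox_fit
  if (is.null(cox_final)) stop("Cox model degenerate on the augmented set")
  partition <- classify_risk(cox_final, data, threshold_rule = threshold_rule)
  aft_final <- fit_aft_l12(augmented, h_star = h(augmented$time),
                           lambda = "cv", nfolds = nfolds, seed = seed + 2000,
                           cv_eligible = rep(TRUE, nrow(augmented)),
                           n_lambda = n_lambda,
                           lambda_min_ratio = lambda_min_ratio, h = h)
  structure(list(
    cox_fit = cox_final,
    aft_fit = aft_final,
    partition = partition,
    augmented = augmented,
    validated = validated,
    excluded_ids = setdiff(censored$sample_id, validated$sample_id),
    iterations = dplyr::bind_rows(logs),
    converged = converged,
    config = list(max_iters = max_iters, nfolds = nfolds, seed = seed,
                  threshold_rule = threshold_rule, n_lambda = n_lambda,
                  lambda_min_ratio = lambda_min_ratio,
                  restrict_aft_to_cox = restrict_aft_to_cox)
  ), class = "semisup_result")
}

augment_training <- function(complete, censored, validated) {
  if (!nrow(validated)) return(complete)
  add <- censored[match(validated$sample_id, censored$sample_id), , drop = FALSE]
  add$time <- validated$imputed_time
  add$status <- 1L
  dplyr::bind_rows(complete, add)
}

iteration_log <- function(iter, train, validated, censored, cox_fit, aft_fit,
                          n_error) {
  tibble::tibble(
    iteration = iter,
    n_train = nrow(train),
    n_censored = nrow(censored),
    n_validated = nrow(validated),
    n_error = as.integer(n_error),
    cox_lambda = cox_fit$lambda,
    cox_selected = length(cox_fit$selected),
    aft_lambda = if (is.null(aft_fit)) NA_real_ else aft_fit$lambda,
    aft_selected = if (is.null(aft_fit)) NA_integer_ else length(aft_fit$selected)
  )
}

#' @export
print.semisup_result <- function(x, ...) {
  cat("Semi-supervised Cox/AFT result (", nrow(x$iterations), " iteration(s)",
      if (x$converged) ", converged" else "", ")\n", sep = "")
  cat("augmented training set:", nrow(x$augmented), "samples (",
      nrow(x$validated), "validated imputations,", length(x$excluded_ids),
      "excluded )\n")
  cat("Cox selected", length(x$cox_fit$selected), "genes; AFT selected",
      length(x$aft_fit$selected), "genes\n")
  invisible(x)
}

#' Compare single Cox, single AFT and the semi-supervised pipeline
#'
#' On a simulated dataset with known truth, fits (a) the single Cox model on
#' complete samples only, (b) the single AFT model with global Kaplan-Meier
#' conditional-mean imputation and no risk classes, and (c) the
#' semi-supervised pipeline, then reports gene-selection counts and
#' precision for each selection, risk-classification accuracy against the
#' true median split of the true linear predictor, and the fraction of
#' censored samples never validated. With a `test` dataset, concordance
#' index and integrated Brier score on the held-out samples are added.
#'
#' @param sim A `sim_surv` object from [simulate_survival()].
#' @param test Optional second `sim_surv` object used as a test set.
#' @param nfolds,seed,max_iters,n_lambda,lambda_min_ratio Passed through to
#'   the fitters and [run_semisupervised()].
#' @param evaluate_test Compute CI/IBS on `test` (default TRUE when given).
#' @return A one-row tibble of comparison metrics; the fitted objects are
#'   attached as the `"fits"` attribute.
#' @export
compare_single_vs_semi <- function(sim, test = NULL, nfolds = 5, seed = 1,
                                   max_iters = 5, n_lambda = 20,
                                   lambda_min_ratio = 0.08,
                                   evaluate_test = !is.null(test)) {
  stopifnot(inherits(sim, "sim_surv"))
  data <- sim$data
  truth <- sim$true_support
  complete <- data[data$status == 1, , drop = FALSE]
  n_cens <- sum(data$status == 0)

  cox_single <- cox_fit_active(complete, nfolds, seed, n_lambda, lambda_min_ratio)
  aft_single <- fit_aft_l12(data, lambda = "cv", nfolds = nfolds, seed = seed + 1,
                            n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio)
  semi <- run_semisupervised(data, max_iters = max_iters, nfolds = nfolds,
                             seed = seed, n_lambda = n_lambda,
                             lambda_min_ratio = lambda_min_ratio)

  eta_true <- drop(feature_matrix(data) %*% sim$beta_true)
  true_high <- eta_true > median(eta_true)
  acc <- function(fit) {
    if (is.null(fit)) return(NA_real_)
    part <- classify_risk(fit, data)
    mean((part$risk == "high") == true_high)
  }
  prec <- function(sel) selection_precision(sel, truth)

  row <- dplyr::bind_cols(
    stats::setNames(prec(if (is.null(cox_single)) character(0) else cox_single$selected),
                    c("cox_correct", "cox_selected", "cox_precision")),
    stats::setNames(prec(semi$cox_fit$selected),
                    c("semi_cox_correct", "semi_cox_selected", "semi_cox_precision")),
    stats::setNames(prec(aft_single$selected),
                    c("aft_correct", "aft_selected", "aft_precision")),
    stats::setNames(prec(semi$aft_fit$selected),
                    c("semi_aft_correct", "semi_aft_selected", "semi_aft_precision")),
    tibble::tibble(
      acc_cox = acc(cox_single),
      acc_semi_cox = mean((semi$partition$risk == "high") == true_high),
      pct_unvalidated = if (n_cens > 0) 100 * length(semi$excluded_ids) / n_cens else NA_real_,
      n_iterations = nrow(semi$iterations),
      semisup_converged = semi$converged
    )
  )
  if (evaluate_test && !is.null(test)) {
    td <- test$data
    ci <- function(fit, orient) {
      if (is.null(fit)) return(NA_real_)
      concordance_index(td, orient * predict(fit, td, type = "lp"))
    }
    ibs <- function(fit) {
      if (is.null(fit)) return(NA_real_)
      integrated_brier(td, survival_curves(fit, td))
    }
    row <- dplyr::bind_cols(row, tibble::tibble(
      ci_cox = ci(cox_single, -1), ci_semi_cox = ci(semi$cox_fit, -1),
      ci_aft = ci(aft_single, 1), ci_semi_aft = ci(semi$aft_fit, 1),
      ibs_cox = ibs(cox_single), ibs_semi_cox = ibs(semi$cox_fit),
      ibs_aft = ibs(aft_single), ibs_semi_aft = ibs(semi$aft_fit)
    ))
  }
  attr(row, "fits") <- list(cox_single = cox_single, aft_single = aft_single,
                            semi = semi)
  row
}
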