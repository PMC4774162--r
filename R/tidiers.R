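#' Tidy an L1/2 Cox fit
#'
#' @param x A `cox_l12` fit.
#' @param nonzero_only Keep only selected (nonzero) coefficients.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` (original covariate scale).
#' @export
tidy.cox_l12 <- function(x, nonzero_only = FALSE, ...) {
  out <- tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
  if (nonzero_only) out <- out[out$estimate != 0, , drop = FALSE]
  out
}

#' @rdname tidy.cox_l12
#' @export
tidy.aft_l12 <- function(x, nonzero_only = FALSE, ...) {
  out <- tibble::tibble(term = c("(Intercept)", names(x$beta)),
                        estimate = c(x$intercept, unname(x$beta)))
  if (nonzero_only) {
    out <- out[out$term == "(Intercept)" | out$estimate != 0, , drop = FALSE]
  }
  out
}

#' One-row summary of an L1/2 Cox fit
#'
#' @param x A `cox_l12` fit.
#' @param ... Unused.
#' @return A one-row tibble: penalty, support size, scaled log partial
#'   likelihood, sample and event counts.
#' @export
glance.cox_l12 <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_selected = length(x$selected),
                 loglik = x$loglik, nobs = x$nobs, nevents = x$nevents)
}

#' @rdname glance.cox_l12
#' @export
glance.aft_l12 <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_selected = length(x$selected),
                 intercept = x$intercept, nobs = x$nobs)
}

#' Per-iteration log of a semi-supervised run
#'
#' @param x A `semisup_result`.
#' @param ... Unused.
#' @return The iteration log tibble (training size, validated/error counts,
#'   penalties and support sizes per iteration).
#' @export
tidy.semisup_result <- function(x, ...) x$iterations

#' @rdname tidy.semisup_result
#' @export
glance.semisup_result <- function(x, ...) {
  tibble::tibble(n_iterations = nrow(x$iterations),
                 converged = x$converged,
                 n_augmented = nrow(x$augmented),
                 n_validated = nrow(x$validated),
                 n_excluded = length(x$excluded_ids),
                 cox_selected = length(x$cox_fit$selected),
                 aft_selected = length(x$aft_fit$selected))
}

#' Add risk classes and scores to a dataset
#'
#' @param x A `cox_l12` fit.
#' @param data A survival tibble to score.
#' @param ... Unused.
#' @return `data` with `.score` (prognostic index) and `.risk` columns.
#' @export
augment.cox_l12 <- function(x, data, ...) {
  part <- classify_risk(x, data)
  dplyr::mutate(data, .score = part$score, .risk = part$risk)
}

#' Per-setting summary of a simulation experiment
#'
#' @param x A `sim_experiment`.
#' @param ... Unused.
#' @return The per-setting summary tibble (means and sds over replicates).
#' @export
tidy.sim_experiment <- function(x, ...) x$summary
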