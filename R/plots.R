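#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_estimator()].
#' @param ... Unused.
#' @return A ggplot step plot of the product-limit estimate.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                         tibble::tibble(time = object$time, surv = object$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  title = "Kaplan-Meier estimate") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation curve of a penalized fit
#'
#' @param object A `cox_l12` or `aft_l12` fit tuned with `lambda = "cv"`.
#' @param ... Unused.
#' @return A ggplot of the CV criterion against log(lambda), with the
#'   selected penalty marked.
#' @export
autoplot.cox_l12 <- function(object, ...) {
  cv_plot(object$cv, object$lambda, "cross-validated partial likelihood", "cvpl")
}

#' @rdname autoplot.cox_l12
#' @export
autoplot.aft_l12 <- function(object, ...) {
  cv_plot(object$cv, object$lambda, "held-out mean squared error", "mse")
}

cv_plot <- function(cv, lambda, ylab, col) {
  if (is.null(cv)) stop("fit was not tuned by cross-validation; no CV curve to plot")
  ggplot2::ggplot(cv, ggplot2::aes(x = log(.data$lambda), y = .data[[col]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = log(lambda), linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a risk partition
#'
#' @param object A `risk_partition` from [classify_risk()].
#' @param ... Unused.
#' @return A ggplot histogram of prognostic scores coloured by risk class,
#'   with the classification threshold marked.
#' @export
autoplot.risk_partition <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score, fill = .data$risk)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "prognostic index", y = "samples") +
    ggplot2::theme_minimal()
}

#' Plot the sample flow of a semi-supervised run
#'
#' @param object A `semisup_result`.
#' @param ... Unused.
#' @return A ggplot of training-set growth and validated/error counts per
#'   iteration.
#' @export
autoplot.semisup_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$iterations[c("iteration", "n_train", "n_validated", "n_error")],
    -"iteration", names_to = "count", values_to = "samples")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$samples,
                                     colour = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$iterations$iteration) +
    ggplot2::labs(x = "iteration", y = "samples") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by risk class
#'
#' Draws the product-limit curves of the two risk classes of a partition on
#' the original observed data; under an informative prognostic index the
#' high-risk curve lies below the low-risk curve.
#'
#' @param partition A `risk_partition`.
#' @param data The survival tibble the partition refers to.
#' @return A ggplot with one step curve per risk class.
#' @export
plot_risk_km <- function(partition, data) {
  data <- validate_survival_data(data)
  dfs <- lapply(levels(partition$risk), function(cl) {
    ids <- partition$sample_id[partition$risk == cl]
    sub <- data[data$sample_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    cv <- km_estimator(sub$time, sub$status)
    tibble::tibble(time = c(0, cv$time), surv = c(1, cv$surv), risk = cl)
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$risk)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}
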