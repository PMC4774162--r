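test_that("imputation validation demands strictly later survival", {
  expect_identical(validate_imputations(c(5, 7, 6), c(6, 6, 6)),
                   c(FALSE, TRUE, FALSE))
  expect_error(validate_imputations(1:3, 1:2), "lengths differ")
})

test_that("with no censored samples the loop degenerates to single fits", {
  sim <- simulate_survival(n = 60, p = 12, n_informative = 3,
                           censor_rate = 0.1, seed = 71)
  d <- dplyr::mutate(sim$data, status = 1L)
  res <- run_semisupervised(d, seed = 5)
  expect_equal(nrow(res$iterations), 1)
  expect_true(res$converged)
  expect_equal(nrow(res$augmented), nrow(d))
  expect_length(res$excluded_ids, 0)
  single_cox <- fit_cox_l12(d, lambda = "cv", seed = 5)
  expect_equal(res$cox_fit$beta, single_cox$beta)
  single_aft <- fit_aft_l12(d, h_star = log(d$time), lambda = "cv",
                            seed = 5 + 2000,
                            cv_eligible = rep(TRUE, nrow(d)))
  expect_equal(res$aft_fit$beta, single_aft$beta)
})

test_that("failed validations leave the training set at the complete samples", {
  sim <- simulate_survival(n = 80, p = 10, n_informative = 3, seed = 72)
  d <- sim$data
  # censor far beyond every event time: no AFT estimate can exceed it
  far <- 1e6 * max(d$time)
  d$time[d$status == 0] <- far
  res <- run_semisupervised(d, seed = 2)
  expect_equal(nrow(res$validated), 0)
  expect_setequal(res$excluded_ids, d$sample_id[d$status == 0])
  expect_equal(sort(res$augmented$sample_id),
               sort(d$sample_id[d$status == 1]))
})

test_that("the augmented set preserves complete samples and grows monotonically", {
  sim <- simulate_survival(n = 150, p = 30, n_informative = 5, seed = 73)
  res <- run_semisupervised(sim$data, seed = 3)
  complete_ids <- sim$data$sample_id[sim$data$status == 1]
  expect_true(all(complete_ids %in% res$augmented$sample_id))
  orig <- sim$data[sim$data$status == 1, ]
  kept <- res$augmented[match(orig$sample_id, res$augmented$sample_id), ]
  expect_equal(kept$time, orig$time)
  expect_gte(nrow(res$augmented), length(complete_ids))
  # validated imputations strictly exceed their censoring times and enter as events
  if (nrow(res$validated)) {
    expect_true(all(res$validated$imputed_time > res$validated$censored_time))
    added <- res$augmented[match(res$validated$sample_id, res$augmented$sample_id), ]
    expect_true(all(added$status == 1L))
    expect_equal(added$time, res$validated$imputed_time)
  }
  expect_true(length(intersect(res$excluded_ids, res$augmented$sample_id)) == 0)
})

test_that("identical seeds reproduce the whole semi-supervised result", {
  sim <- simulate_survival(n = 100, p = 20, n_informative = 4, seed = 74)
  r1 <- run_semisupervised(sim$data, seed = 9)
  r2 <- run_semisupervised(sim$data, seed = 9)
  expect_equal(r1$cox_fit$beta, r2$cox_fit$beta)
  expect_equal(r1$aft_fit$beta, r2$aft_fit$beta)
  expect_identical(r1$validated, r2$validated)
  expect_identical(r1$iterations, r2$iterations)
})

test_that("one sample's covariates cannot leak into another's imputation", {
  sim <- simulate_survival(n = 80, p = 6, n_informative = 2, seed = 75)
  d <- sim$data
  imp1 <- km_mean_impute(d)
  cens_idx <- which(d$status == 0)
  d2 <- d
  d2[cens_idx[1], feature_names(d)] <- as.list(rnorm(6) * 10)
  imp2 <- km_mean_impute(d2)
  expect_equal(imp1$h_star, imp2$h_star, tolerance = 1e-12)
})

test_that("the comparison report contrasts single and semi-supervised models", {
  sim <- simulate_survival(n = 90, p = 25, n_informative = 4, seed = 76)
  test_sim <- simulate_survival(n = 60, p = 25, n_informative = 4, seed = 77)
  cmp <- compare_single_vs_semi(sim, test = test_sim, seed = 6)
  expect_equal(nrow(cmp), 1)
  needed <- c("cox_correct", "cox_selected", "cox_precision",
              "semi_cox_correct", "semi_cox_selected", "semi_cox_precision",
              "aft_precision", "semi_aft_precision", "acc_cox",
              "acc_semi_cox", "pct_unvalidated", "ci_cox", "ci_semi_cox",
              "ibs_cox", "ibs_semi_aft")
  expect_true(all(needed %in% names(cmp)))
  expect_true(all(dplyr::between(
    unlist(cmp[c("ci_cox", "ci_semi_cox", "ci_aft", "ci_semi_aft")]), 0, 1)))
  expect_gte(cmp$pct_unvalidated, 0)
  expect_lte(cmp$pct_unvalidated, 100)
  fits <- attr(cmp, "fits")
  expect_s3_class(fits$semi, "semisup_result")
})

test_that("iteration logs track training growth and model sizes", {
  sim <- simulate_survival(n = 100, p = 15, n_informative = 3, seed = 78)
  res <- run_semisupervised(sim$data, seed = 4, max_iters = 3)
  log <- tidy(res)
  expect_true(all(c("iteration", "n_train", "n_validated", "n_error",
                    "cox_lambda", "cox_selected", "aft_lambda",
                    "aft_selected") %in% names(log)))
  expect_lte(nrow(log), 3)
  expect_equal(log$n_train[1], sum(sim$data$status == 1))
  g <- glance(res)
  expect_equal(g$n_excluded + g$n_validated, sum(sim$data$status == 0))
})
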