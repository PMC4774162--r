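test_that("the product-limit curve matches the hand example", {
  km <- km_estimator(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km$surv, c(0.75, 0.75, 0.375, 0), tolerance = 1e-12)
  expect_equal(km$step, c(0.25, 0, 0.375, 0.375), tolerance = 1e-12)
  expect_equal(km$n_risk, c(4L, 3L, 2L, 1L))
})

test_that("KM reduces to the empirical survivor without censoring", {
  t <- c(3, 1, 4, 2, 5)
  km <- km_estimator(t, rep(1, 5))
  expect_equal(km$surv, 1 - (1:5) / 5, tolerance = 1e-12)
  expect_equal(sum(km$step), 1, tolerance = 1e-12) # largest observation is an event
  # all censored: flat curve, no drops
  km0 <- km_estimator(t, rep(0, 5))
  expect_true(all(km0$surv == 1))
  expect_true(all(km0$n_event == 0))
})

test_that("KM agrees with survival::survfit on censored data", {
  library(survival)
  set.seed(8)
  t <- round(rexp(40), 2) + 0.01
  s <- rbinom(40, 1, 0.6)
  km <- km_estimator(t, s)
  sf <- summary(survfit(Surv(t, s) ~ 1), times = km$time)
  expect_equal(km$surv, sf$surv, tolerance = 1e-10)
})

test_that("conditional-mean imputation reproduces the hand-evaluated value", {
  d <- toy_km_data()
  imp <- km_mean_impute(d)
  expect_equal(imp$h_star[2], (log(3) * 0.375 + log(4) * 0.375) / 0.75,
               tolerance = 1e-12)
  expect_equal(imp$h_star[2], 1.2425, tolerance = 1e-4)
  expect_equal(exp(imp$h_star[2]), 3.464, tolerance = 1e-3)
  expect_equal(imp$h_star[c(1, 3, 4)], log(c(1, 3, 4)), tolerance = 1e-12)
  expect_equal(imp$was_imputed, c(FALSE, TRUE, FALSE, FALSE))
  expect_false(any(imp$undefined_tail))
})

test_that("events pass through and tail censorings are flagged", {
  d <- tibble::tibble(time = c(1, 2, 3, 5), status = c(1L, 1L, 1L, 0L),
                      g1 = rnorm(4))
  imp <- km_mean_impute(d)
  expect_true(imp$undefined_tail[4])
  expect_equal(imp$h_star[4], log(3), tolerance = 1e-12) # last-event fallback
  d_ev <- dplyr::mutate(d, status = 1L)
  imp_ev <- km_mean_impute(d_ev)
  expect_equal(imp_ev$h_star, log(d_ev$time), tolerance = 1e-12)
  expect_false(any(imp_ev$was_imputed))
})

test_that("defined imputations strictly exceed the censored response", {
  sim <- simulate_survival(n = 120, p = 5, n_informative = 2, seed = 51)
  imp <- km_mean_impute(sim$data)
  idx <- imp$was_imputed & !imp$undefined_tail
  expect_true(all(imp$h_star[idx] > log(imp$time[idx])))
})

test_that("a censored time tying an event uses strictly later events only", {
  d <- tibble::tibble(time = c(1, 2, 2, 3), status = c(1L, 1L, 0L, 1L),
                      g1 = rnorm(4))
  imp <- km_mean_impute(d)
  # only the event at t = 3 lies strictly beyond the censoring at t = 2
  expect_equal(imp$h_star[3], log(3), tolerance = 1e-12)
})

test_that("large penalties give the intercept-only AFT model", {
  sim <- simulate_survival(n = 50, p = 8, n_informative = 2, seed = 52)
  h_star <- km_mean_impute(sim$data)$h_star
  fit <- fit_aft_l12(sim$data, h_star = h_star, lambda = 50)
  expect_length(fit$selected, 0)
  expect_equal(fit$intercept, mean(h_star), tolerance = 1e-12)
  expect_equal(predict_log_time(fit, sim$data), rep(fit$intercept, 50),
               tolerance = 1e-12)
})

test_that("the unpenalized AFT fit equals ordinary least squares", {
  sim <- simulate_survival(n = 50, p = 3, n_informative = 2, seed = 53)
  d <- sim$data
  fit <- fit_aft_l12(d, h_star = log(d$time), lambda = 0)
  ols <- lm(log(time) ~ g1 + g2 + g3, data = d)
  expect_equal(c(fit$intercept, unname(fit$beta)), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("noiseless responses are interpolated at a vanishing penalty", {
  set.seed(54)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- 1.5 + drop(X %*% c(1, -2, 0.5, 0))
  d <- dplyr::bind_cols(tibble::tibble(time = exp(y), status = 1L),
                        tibble::as_tibble(X))
  fit <- fit_aft_l12(d, h_star = y, lambda = 1e-8)
  expect_equal(predict_log_time(fit, d), y, tolerance = 1e-6)
  expect_equal(unname(predict(fit, d, type = "time")), exp(y), tolerance = 1e-4)
})

test_that("with zero censoring the pipeline is penalized least squares on log-times", {
  sim <- simulate_survival(n = 60, p = 10, n_informative = 3,
                           censor_rate = 0.01, seed = 55)
  d <- sim$data
  d$status <- 1L
  fit_pipe <- fit_aft_l12(d, lambda = 0.1) # h_star defaults to imputation
  fit_direct <- fit_aft_l12(d, h_star = log(d$time), lambda = 0.1)
  expect_equal(fit_pipe$beta, fit_direct$beta, tolerance = 1e-12)
  expect_equal(fit_pipe$intercept, fit_direct$intercept, tolerance = 1e-12)
})

test_that("AFT cross-validation honours single candidates and finds signal", {
  sim <- simulate_survival(n = 80, p = 10, n_informative = 3, seed = 56)
  h_star <- km_mean_impute(sim$data)$h_star
  cv1 <- cv_tune_aft(sim$data, h_star, lambdas = 0.2, seed = 1)
  expect_equal(cv1$lambda, 0.2)
  cv <- cv_tune_aft(sim$data, h_star, seed = 1)
  fit <- fit_aft_l12(sim$data, h_star = h_star, lambda = cv$lambda)
  expect_gte(length(intersect(fit$selected, sim$true_support)), 2)
  # pure noise tunes to the sparse top of the grid
  simn <- simulate_survival(n = 80, p = 20, n_informative = 0, seed = 57)
  hn <- km_mean_impute(simn$data)$h_star
  cvn <- cv_tune_aft(simn$data, hn, seed = 2, n_lambda = 10)
  seln <- cvn$cv_table$n_selected[cvn$cv_table$lambda == cvn$lambda]
  expect_lte(seln, 2)
})
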