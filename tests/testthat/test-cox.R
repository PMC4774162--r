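# Independent reference: direct risk-set enumeration of the Breslow log
# partial likelihood, deliberately written differently from the package's
# cumulative-sum implementation.
naive_cox_pl <- function(beta, data) {
  X <- feature_matrix(data)
  eta <- drop(X %*% beta)
  total <- 0
  for (i in seq_len(nrow(data))) {
    if (data$status[i] == 1) {
      risk <- data$time >= data$time[i]
      total <- total + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  unname(total) / nrow(data)
}

test_that("null partial likelihood matches the risk-set sizes", {
  d <- toy_cox_data()
  expect_equal(cox_partial_loglik(d, c(g1 = 0)),
               (log(1 / 3) + log(1 / 2) + log(1)) / 3, tolerance = 1e-12)
  expect_equal(cox_partial_loglik(d, c(g1 = 0)), -0.5973, tolerance = 1e-4)
})

test_that("partial likelihood is zero with no events and matches enumeration", {
  d <- toy_km_data()
  d0 <- dplyr::mutate(d, status = 0L)
  expect_identical(cox_partial_loglik(d0, c(g1 = 1, g2 = -1)), 0)
  set.seed(3)
  d5 <- tibble::tibble(time = c(2, 5, 1, 8, 3), status = c(1L, 0L, 1L, 1L, 0L),
                       g1 = c(0.3, -0.8, 1.2, 0.1, -0.5))
  for (b in c(-1, 0.5, 2)) {
    expect_equal(cox_partial_loglik(d5, c(g1 = b)),
                 naive_cox_pl(c(g1 = b), validate_survival_data(d5)),
                 tolerance = 1e-10)
  }
})

test_that("partial likelihood is invariant to feature centering", {
  d <- toy_km_data()
  b <- c(g1 = 0.7, g2 = -0.3)
  d_shift <- dplyr::mutate(d, g1 = g1 + 100)
  expect_equal(cox_partial_loglik(d, b), cox_partial_loglik(d_shift, b),
               tolerance = 1e-9)
})

test_that("a large penalty returns the null model with its null likelihood", {
  sim <- simulate_survival(n = 50, p = 10, n_informative = 3, seed = 41)
  fit <- fit_cox_l12(sim$data, lambda = 100)
  expect_length(fit$selected, 0)
  expect_equal(fit$loglik,
               cox_partial_loglik(sim$data, rep(0, 10)), tolerance = 1e-12)
})

test_that("the unpenalized fit matches an independent Newton solver", {
  library(survival)
  sim <- simulate_survival(n = 60, p = 3, n_informative = 2, seed = 11)
  fit <- fit_cox_l12(sim$data, lambda = 0)
  oracle <- coxph(Surv(time, status) ~ g1 + g2 + g3, data = sim$data,
                  ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-3)
})

test_that("Breslow baseline collapses to Nelson-Aalen at beta = 0", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), status = 1L, g1 = c(0.1, -0.2, 0.3, 0))
  fit <- fit_cox_l12(d, lambda = 50) # penalty large enough for beta = 0
  bl <- breslow_baseline(fit, d)
  expect_equal(bl$cumhaz, cumsum(1 / (4:1)), tolerance = 1e-12)
  # hand evaluation with one censored sample: risk sets 4, 2 at events 1, 3
  d2 <- toy_km_data()
  fit2 <- fit_cox_l12(d2, lambda = 50)
  bl2 <- breslow_baseline(fit2, d2)
  expect_equal(bl2$time, c(1, 3, 4))
  expect_equal(bl2$cumhaz, c(1 / 4, 1 / 4 + 1 / 2, 1 / 4 + 1 / 2 + 1),
               tolerance = 1e-12)
})

test_that("predicted survival starts at 1 and decreases with risk", {
  sim <- simulate_survival(n = 80, p = 5, n_informative = 2, seed = 43)
  fit <- fit_cox_l12(sim$data, lambda = 0.05)
  S <- predict(fit, sim$data, type = "survival", times = c(0, quantile(sim$data$time, c(0.25, 0.5, 0.75))))
  expect_true(all(S[, 1] == 1))
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(diff(t(S)) <= 1e-12)) # non-increasing in t per sample
})

test_that("risk classification splits at the training median and orders by score", {
  d <- tibble::tibble(time = c(5, 4, 2, 1), status = 1L,
                      g1 = c(-2, -1, 1, 2))
  fit <- fit_cox_l12(d, lambda = 0.01)
  expect_gt(fit$beta[["g1"]], 0) # higher g1, shorter survival
  part <- classify_risk(fit, d)
  expect_equal(as.character(part$risk), c("low", "low", "high", "high"))
  expect_equal(sum(part$risk == "high"), 2)
  fit0 <- fit_cox_l12(d, lambda = 50)
  expect_error(classify_risk(fit0, d), "smaller lambda")
})

test_that("high-risk class carries the higher event rate on simulated data", {
  sim <- simulate_survival(n = 200, p = 10, n_informative = 3, seed = 44)
  fit <- fit_cox_l12(sim$data, lambda = "cv", seed = 3)
  part <- classify_risk(fit, sim$data)
  km_hi <- km_estimator(sim$data$time[part$risk == "high"],
                        sim$data$status[part$risk == "high"])
  km_lo <- km_estimator(sim$data$time[part$risk == "low"],
                        sim$data$status[part$risk == "low"])
  t_med <- median(sim$data$time)
  expect_lt(semisurv:::km_surv_at(km_hi, t_med),
            semisurv:::km_surv_at(km_lo, t_med))
})

test_that("cross-validation honours a single candidate and prefers sparse ties", {
  sim <- simulate_survival(n = 60, p = 8, n_informative = 2, seed = 45)
  cv <- cv_tune_cox(sim$data, lambdas = 0.07, seed = 1)
  expect_equal(cv$lambda, 0.07)
  expect_equal(nrow(cv$cv_table), 1)
})

test_that("pure-noise data tunes to (or near) the null end of the path", {
  sim <- simulate_survival(n = 80, p = 30, n_informative = 0, seed = 46)
  cv <- cv_tune_cox(sim$data, seed = 2, n_lambda = 10)
  # lambda* sits in the sparse top of the grid
  expect_gte(cv$lambda, sort(cv$cv_table$lambda, decreasing = TRUE)[3])
  sel <- cv$cv_table$n_selected[cv$cv_table$lambda == cv$lambda]
  expect_lte(sel, 2)
})

test_that("strong signals are recovered by the tuned fit", {
  sim <- simulate_survival(n = 150, p = 40, n_informative = 5, seed = 47)
  fit <- fit_cox_l12(sim$data, lambda = "cv", seed = 4)
  expect_gte(length(intersect(fit$selected, sim$true_support)), 4)
})
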