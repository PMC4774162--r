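test_that("half-thresholding matches its closed-form special cases", {
  expect_identical(half_threshold(1, 0), 1)
  expect_identical(half_threshold(-2.5, 0), -2.5)
  # below the operator boundary 54^(1/3)/4 ~ 0.9449 the output is zero
  expect_identical(half_threshold(0.1, 1), 0)
  expect_equal(threshold_boundary(1), 54^(1 / 3) / 4, tolerance = 1e-12)
  expect_equal(threshold_boundary(1), 0.944940, tolerance = 1e-6)
  expect_identical(threshold_boundary(0), 0)
  expect_equal(threshold_boundary(8), 54^(1 / 3), tolerance = 1e-12)
  expect_error(half_threshold(1, -1), "nonnegative")
})

test_that("exact zero at the boundary, odd symmetry, and shrinkage", {
  lam <- 1.3
  b <- threshold_boundary(lam)
  expect_identical(half_threshold(b, lam), 0) # tie broken to zero
  expect_gt(abs(half_threshold(b + 1e-9, lam)), 0)
  om <- seq(-3, 3, length.out = 41)
  expect_equal(half_threshold(-om, lam), -half_threshold(om, lam))
  expect_true(all(abs(half_threshold(om, lam)) <= abs(om)))
  expect_true(all(abs(half_threshold(om, 0.5)) < abs(om) | om == 0))
})

test_that("the operator solves the scalar subproblem found by brute force", {
  # minimizer of (1/2)(b-om)^2 + lam*sqrt(|b|) is half_threshold(om, 2*lam)
  set.seed(42)
  for (i in 1:300) {
    om <- runif(1, -3, 3)
    lam <- runif(1, 0, 2)
    expect_equal(half_threshold(om, 2 * lam), brute_half_min(om, lam),
                 tolerance = 2e-3)
  }
  # and the operator value never does worse than staying at zero
  om <- runif(500, -4, 4)
  lam <- runif(500, 0, 3)
  bt <- half_threshold(om, 2 * lam)
  expect_true(all(0.5 * (bt - om)^2 + lam * sqrt(abs(bt)) <= 0.5 * om^2 + 1e-12))
})

test_that("coordinate descent zeroes everything above lambda_max", {
  sim <- simulate_survival(n = 40, p = 8, n_informative = 2, seed = 21)
  std <- standardize_features(sim$data)
  Xs <- feature_matrix(std$data)
  y <- log(sim$data$time)
  yc <- y - mean(y)
  lmax <- lambda_path(Xs, yc, n_lambda = 1)
  fit <- coordinate_descent_l12(Xs, yc, lmax)
  expect_true(all(fit$beta == 0))
  expect_true(fit$converged)
  fit2 <- coordinate_descent_l12(Xs, yc, lmax * 1.5)
  expect_true(all(fit2$beta == 0))
})

test_that("orthogonal designs decouple into componentwise thresholding", {
  # columns orthogonal with sum of squares n = 3
  Xs <- sqrt(3) * diag(3)
  y <- c(2, -1.2, 0.4)
  lam <- 0.3
  fit <- coordinate_descent_l12(Xs, y, lam)
  omega <- drop(crossprod(Xs, y)) / 3
  expect_equal(unname(fit$beta), half_threshold(omega, 2 * lam),
               tolerance = 1e-10)
})

test_that("noiseless sparse signals are recovered exactly on the path", {
  set.seed(77)
  n <- 50
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("g", 1:10)))
  Xc <- sweep(X, 2, colMeans(X))
  Xs <- sweep(Xc, 2, sqrt(colMeans(Xc^2)), "/")
  beta_true <- c(2, -1.5, 1, rep(0, 7))
  y <- drop(Xs %*% beta_true)
  lams <- lambda_path(Xs, y, n_lambda = 20, ratio = 0.01)
  hit <- FALSE
  beta <- NULL
  for (l in lams) {
    fit <- coordinate_descent_l12(Xs, y, l, beta_init = beta)
    beta <- fit$beta
    if (setequal(which(beta != 0), which(beta_true != 0))) hit <- TRUE
  }
  expect_true(hit)
})

test_that("the objective trace is non-increasing sweep to sweep", {
  sim <- simulate_survival(n = 60, p = 30, n_informative = 5, seed = 23)
  std <- standardize_features(sim$data)
  Xs <- feature_matrix(std$data)
  yc <- log(sim$data$time) - mean(log(sim$data$time))
  for (lam in c(0.01, 0.05, 0.2)) {
    fit <- coordinate_descent_l12(Xs, yc, lam)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
  w <- runif(60, 0.5, 2)
  fitw <- coordinate_descent_l12(Xs, yc, 0.05, weights = w)
  expect_true(all(diff(fitw$objective_trace) <= 1e-10))
})

test_that("lambda_path spans a descending grid anchored at lambda_max", {
  Xs <- matrix(sqrt(5) * diag(5)[, 1], 5, 1) # single unit-scaled feature
  y <- Xs[, 1] * 0.7
  lams <- lambda_path(Xs, y, n_lambda = 7, ratio = 0.1)
  expect_length(lams, 7)
  expect_true(all(diff(lams) < 0))
  expect_equal(lams[7], 0.1 * lams[1], tolerance = 1e-10)
  # fitting exactly at lambda_max from zero start gives the null model
  fit <- coordinate_descent_l12(Xs, y, lams[1])
  expect_true(all(fit$beta == 0))
  # one notch below, the feature enters
  fit2 <- coordinate_descent_l12(Xs, y, lams[2])
  expect_gt(sum(fit2$beta != 0), 0)
  expect_error(lambda_path(Xs, rep(0, 5)), "orthogonal")
})
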