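# Small deterministic fixtures shared across test files.

# Report every failure rather than stopping at testthat's default cap: the
# acceptance checks are allowed to fail as a group without masking the
# results of the files that run after them.
options(testthat.max_fails = Inf)

# Four samples, one censored at t = 2; the classic product-limit example.
toy_km_data <- function() {
  tibble::tibble(
    sample_id = paste0("s", 1:4),
    time = c(1, 2, 3, 4),
    status = c(1L, 0L, 1L, 1L),
    g1 = c(0.5, -0.2, 1.1, 0.3),
    g2 = c(-1.0, 0.4, 0.2, 0.9)
  )
}

# Three events, no censoring, one feature: null partial likelihood is
# (1/3) * (log(1/3) + log(1/2) + log(1)).
toy_cox_data <- function() {
  tibble::tibble(time = c(1, 2, 3), status = 1L, g1 = c(0.5, -1, 0.2))
}

# Brute-force scalar minimizer of (1/2)(b - omega)^2 + lam * sqrt(|b|)
# over a sign-aware grid (the minimizer always lies between 0 and omega).
brute_half_min <- function(omega, lam, n_grid = 4000) {
  b <- seq(0, omega, length.out = n_grid)
  obj <- 0.5 * (b - omega)^2 + lam * sqrt(abs(b))
  b[which.min(obj)]
}
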