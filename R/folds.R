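#' Stratified K-fold assignment
#'
#' Assigns samples to K cross-validation folds, stratifying on the event
#' indicator so each fold's censored fraction is within one sample of the
#' overall fraction. An imbalanced censored/event split across folds is the
#' main way partial-likelihood cross-validation destabilises, which is why
#' status (not time) is the stratification variable. Strata are shuffled and
#' dealt round-robin with a running offset, so folds stay non-empty whenever
#' K <= n; strata smaller than K degrade gracefully to plain shuffling.
#'
#' @param data A survival tibble.
#' @param k Number of folds (>= 2, <= n).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A tibble with columns `sample_id` and `fold` (integers in 1..k),
#'   with attributes `k` and `seed`.
#' @export
#' @examples
#' sim <- simulate_survival(n = 20, p = 3, n_informative = 1, seed = 2)
#' table(stratified_kfold(sim$data, k = 5, seed = 1)$fold)
stratified_kfold <- function(data, k = 5, seed = 1) {
  data <- validate_survival_data(data)
  n <- nrow(data)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  fold <- integer(n)
  withr::with_seed(seed, {
    offset <- 0L
    for (s in c(1L, 0L)) {
      idx <- which(data$status == s)
      if (!length(idx)) next
      idx <- sample(idx)
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  out <- tibble::tibble(sample_id = data$sample_id, fold = fold)
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- as.integer(seed)
  out
}
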