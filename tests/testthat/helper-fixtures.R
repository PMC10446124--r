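# small in-code fixtures shared across test files

# deterministic linear dataset with known structure, no generation machinery
tiny_linear_data <- function(n = 40, k = 2, seed = 42, tau2 = 4) {
  set.seed(seed)
  x <- rnorm(n, 0, 3)
  age <- rnorm(n, 50, 6)
  W <- matrix(rnorm(n * k, mean = x, sd = sqrt(tau2)), n, k)
  y <- 1 + 0.5 * x + 0.1 * age + rnorm(n, 0, 0.5)
  study_data(y, W, covariates = cbind(age = age), family = "linear",
             true_exposure = x)
}

# independent brute-force recomputation of the performance metrics
brute_force_metrics <- function(estimates, truth, ci_pairs = NULL) {
  R <- length(estimates)
  bias <- 0
  for (e in estimates) bias <- bias + (e - truth)
  bias <- bias / R
  mse <- 0
  for (e in estimates) mse <- mse + (e - truth)^2
  mse <- mse / R
  m <- sum(estimates) / R
  v <- 0
  for (e in estimates) v <- v + (e - m)^2
  v <- v / (R - 1)
  mcse_bias <- sqrt(v / R)
  s <- 0
  for (e in estimates) s <- s + ((e - truth)^2 - mse)^2
  mcse_mse <- sqrt(s / (R * (R - 1)))
  out <- list(bias = bias, pct_bias = 100 * bias / truth, mse = mse,
              mcse_bias = mcse_bias, mcse_mse = mcse_mse)
  if (!is.null(ci_pairs)) {
    hits <- 0
    for (i in seq_len(nrow(ci_pairs)))
      if (ci_pairs[i, 1] <= truth && truth <= ci_pairs[i, 2]) hits <- hits + 1
    out$coverage <- hits / nrow(ci_pairs)
    out$mcse_coverage <- sqrt(out$coverage * (1 - out$coverage) / nrow(ci_pairs))
  }
  out
}
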