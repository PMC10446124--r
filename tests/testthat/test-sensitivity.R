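test_that("prior sampling matches closed-form moments and quantiles", {
  # point prior: degenerate
  expect_equal(sample_tau_prior(tau_prior("point", 48, n_draws = 10), 1),
               rep(48, 10))
  # symmetric triangular: mean (a + m + b) / 3 = 48
  tri <- tau_prior("triangular", 37, 59, mode = 48, n_draws = 100000)
  x <- sample_tau_prior(tri, 2)
  tri_sd <- sqrt((37^2 + 48^2 + 59^2 - 37 * 48 - 37 * 59 - 48 * 59) / 18)
  expect_lt(abs(mean(x) - 48), 3 * tri_sd / sqrt(length(x)))
  expect_true(all(x >= 37 & x <= 59))
  # uniform inverse CDF at u = 0.5 is the midpoint
  u <- tau_prior("uniform", 10, 30, n_draws = 50000)
  xu <- sample_tau_prior(u, 3)
  expect_lt(abs(median(xu) - 20), 0.15)
})

test_that("triangular sampler's empirical CDF converges to the closed form", {
  tri <- tau_prior("triangular", 37, 59, mode = 48, n_draws = 20000)
  x <- sort(sample_tau_prior(tri, 7))
  cdf <- function(q) ifelse(q < 48,
                            (q - 37)^2 / ((59 - 37) * (48 - 37)),
                            1 - (59 - q)^2 / ((59 - 37) * (59 - 48)))
  ks <- max(abs(seq_along(x) / length(x) - cdf(x)))
  expect_lt(ks, 0.015)
})

test_that("trapezoidal sampling matches a numerical-integration oracle", {
  a <- 2; b <- 4; cc <- 7; d <- 10
  tp <- tau_prior("trapezoidal", a, d, mode_low = b, mode_high = cc,
                  n_draws = 100000)
  x <- sample_tau_prior(tp, 11)
  expect_true(all(x >= a & x <= d))
  h <- 2 / (d + cc - b - a)
  dens <- function(t) ifelse(t < b, h * (t - a) / (b - a),
                             ifelse(t <= cc, h, h * (d - t) / (d - cc)))
  expect_equal(integrate(dens, a, d)$value, 1, tolerance = 1e-6)
  mean_oracle <- integrate(function(t) t * dens(t), a, d)$value
  expect_lt(abs(mean(x) - mean_oracle), 0.03)
})

test_that("prior validation rejects inconsistent bounds", {
  expect_error(tau_prior("triangular", 10, 5, mode = 7), "minimum")
  expect_error(tau_prior("triangular", 5, 10, mode = 12), "mode")
  expect_error(tau_prior("trapezoidal", 1, 10, mode_low = 6, mode_high = 4),
               "mode_low")
  expect_error(tau_prior("uniform", -1, 3), "non-negative")
})

test_that("a point prior degenerates to a single RC correction", {
  d <- tiny_linear_data(n = 80, k = 2, tau2 = 3)
  prior <- tau_prior("point", 2, n_draws = 5)
  res <- run_sensitivity(d, prior, method = "rc", seed = 1)
  direct <- rc_correct(d, error_model(2, "known"))
  expect_true(all(abs(res$draws$estimate - direct$estimate) < 1e-12))
  expect_equal(res$summary$median, direct$estimate)
})

test_that("RC estimates increase deterministically in the drawn tau2; SIMEX is noisier", {
  d <- tiny_linear_data(n = 120, k = 2, tau2 = 3, seed = 6)
  prior <- tau_prior("uniform", 0.5, 4, n_draws = 30)
  rc <- run_sensitivity(d, prior, method = "rc", seed = 4)
  ord <- order(rc$draws$tau2)
  expect_true(all(diff(rc$draws$estimate[ord]) > 0))
  sx <- run_sensitivity(d, prior, method = "simex", seed = 4,
                        simex = simex_config(n_sim = 15))
  # dispersion around a monotone fit of estimate on tau2 exceeds RC's
  resid_spread <- function(dr) sd(residuals(lm(estimate ~ tau2, dr$draws)))
  expect_gt(resid_spread(sx), resid_spread(rc))
})

test_that("failed draws are recorded, not silently dropped", {
  d <- tiny_linear_data(n = 60, k = 2, tau2 = 3)
  v <- conditional_variance(d)
  # prior straddling the conditional variance: upper draws must fail
  prior <- tau_prior("uniform", 0.5 * v, 1.5 * v, n_draws = 40)
  res <- run_sensitivity(d, prior, method = "rc", seed = 2)
  expect_gt(res$summary$n_failed, 0)
  expect_equal(nrow(res$draws), 40)
  expect_true(all(is.na(res$draws$estimate[res$draws$failed])))
  # all draws failing is an error
  bad <- tau_prior("point", 2 * v, n_draws = 3)
  expect_error(run_sensitivity(d, bad, method = "rc", seed = 2), "all .* failed")
})

test_that("probabilistic bias summary pools sampling and prior uncertainty", {
  d <- tiny_linear_data(n = 80, k = 2, tau2 = 3)
  prior <- tau_prior("point", 2, n_draws = 200)
  res <- run_sensitivity(d, prior, method = "rc", seed = 3,
                         bootstrap = bootstrap_config(n_boot = 49, seed = 5))
  s <- res$draws$se[1]
  pb <- probabilistic_bias_summary(res, seed = 9, n_per_draw = 50)
  # point prior: pooled 2.5-97.5 span is the normal 95% span 3.92 * se
  expect_equal(pb$ci_high - pb$ci_low, 2 * qnorm(0.975) * s, tolerance = 0.15)
  # pooled interval at least as wide as the spread of the point estimates
  expect_gte(pb$ci_high - pb$ci_low,
             diff(range(res$draws$estimate[!res$draws$failed])))
  # zero SE collapses to the point estimate
  res0 <- res
  res0$draws$se <- 0
  pb0 <- probabilistic_bias_summary(res0, seed = 9)
  expect_equal(pb0$median, res$draws$estimate[1])
  # missing SEs instruct to enable the bootstrap
  res_nose <- run_sensitivity(d, prior, method = "rc", seed = 3)
  expect_error(probabilistic_bias_summary(res_nose), "bootstrap")
})
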