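test_that("replicate-based tau2 is the mean within-individual variance", {
  d <- study_data(c(0, 0, 0), rbind(c(1, 3), c(2, 2), c(0, 4)))
  em <- estimate_tau2_replicates(d)
  expect_equal(em$tau2, 10 / 3) # per-row variances 2, 0, 8
  expect_equal(em$source, "replicates")
  # identical replicates within each row -> zero
  d0 <- study_data(1:4, matrix(rep(c(5, 6, 7, 8), 2), 4))
  expect_equal(estimate_tau2_replicates(d0)$tau2, 0)
  expect_error(estimate_tau2_replicates(study_data(1:3, matrix(1:3))),
               "insufficient replicates")
})

test_that("tau2 estimator is invariant to replicate permutation and location shift", {
  d <- tiny_linear_data(k = 3)
  t1 <- estimate_tau2_replicates(d)$tau2
  perm <- d
  perm$exposure_replicates <- d$exposure_replicates[, c(3, 1, 2)]
  expect_equal(estimate_tau2_replicates(perm)$tau2, t1)
  shift <- d
  shift$exposure_replicates <- d$exposure_replicates + 100
  expect_equal(estimate_tau2_replicates(shift)$tau2, t1)
  # sampling distribution recovers the generating tau2 (pooled within-variance)
  ests <- vapply(1:200, function(i)
    estimate_tau2_replicates(generate_linear(linear_scenario(), seed = i))$tau2, 1)
  mcse <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 30), 3 * mcse)
})

test_that("conditional variance is the covariate-adjusted replicate variance", {
  d <- study_data(c(0, 0, 0), matrix(c(1, 2, 3)))
  expect_equal(conditional_variance(d), 1)
  # large-n oracle: Var(BP* | Age) = 50 + tau2 = 80, unaffected by gamma
  for (g in c(0, 1)) {
    big <- generate_linear(linear_scenario(gamma = g, n = 100000), seed = 13)
    expect_equal(conditional_variance(big), 80, tolerance = 0.03)
  }
  # rank-deficient covariates rejected
  dd <- study_data(1:5, matrix(rnorm(5)), covariates = cbind(a = 1:5, b = 2 * (1:5)))
  expect_error(conditional_variance(dd), "rank-deficient")
})

test_that("naive fit recovers the exact coefficient on noise-free data", {
  n <- 30
  x <- rnorm(n, 0, 2)
  age <- rnorm(n)
  d <- study_data(5 + 0.2 * x + 0.3 * age, matrix(x), cbind(age = age))
  res <- suppressWarnings(fit_naive(d)) # lm flags the intentionally exact fit
  expect_equal(res$estimate, 0.2, tolerance = 1e-10)
  expect_equal(res$method, "naive")
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("naive fit reports fit failures with context", {
  # single-class logistic outcome
  d <- study_data(rep(0, 20), matrix(rnorm(20)), family = "logistic")
  expect_error(fit_naive(d), "single class")
  # collinear design
  x <- rnorm(20)
  dd <- study_data(rnorm(20), matrix(x), covariates = cbind(z = 2 * x))
  expect_error(fit_naive(dd), "collinear")
})

test_that("regression calibration is the exact de-attenuation ratio", {
  d <- tiny_linear_data(k = 3)
  naive <- fit_naive(d)
  v <- conditional_variance(d)
  for (t2 in c(0, 1, 3, 6)) {
    rc <- rc_correct(d, error_model(t2, "known"))
    # algebraic identity: rc / naive = v / (v - tau2)
    expect_equal(rc$estimate / naive$estimate, v / (v - t2), tolerance = 1e-12)
    expect_equal(rc$diagnostics$lambda, (v - t2) / v)
    # monotone de-attenuation
    if (t2 > 0) expect_gt(abs(rc$estimate), abs(naive$estimate))
  }
  expect_equal(rc_correct(d, error_model(0, "known"))$estimate, naive$estimate)
  # worked ratio: naive 0.5, v = 100, tau2 = 30 -> 0.7143
  fake <- naive; fake$estimate <- 0.5
  expect_equal(0.5 * 100 / (100 - 30), 5 / 7)
  expect_error(rc_correct(d, error_model(v + 1, "known")),
               "non-positive calibration factor")
})

test_that("RC recovers the estimand and naive shows 1 - attenuation bias", {
  reps <- 300
  naive_est <- rc_est <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- generate_linear(linear_scenario(), seed = 1000 + i)
    nv <- fit_naive(d)
    naive_est[i] <- nv$estimate
    rc_est[i] <- rc_correct(d, naive = nv)$estimate
  }
  mcse_rc <- sd(rc_est) / sqrt(reps)
  expect_lt(abs(mean(rc_est) - 0.2), 3 * mcse_rc)
  pct <- 100 * (mean(naive_est) - 0.2) / 0.2
  mcse_pct <- 100 * sd(naive_est) / sqrt(reps) / 0.2
  expect_lt(abs(pct - (-37.5)), 3 * mcse_pct)
})

test_that("Nagelkerke pseudo R-squared has its closed-form limits", {
  set.seed(21)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(x))
  fit <- glm(y ~ x, family = binomial())
  r2 <- nagelkerke_r2(fit)
  expect_true(r2 > 0 && r2 < 1)
  # null model has pseudo R-squared 0
  expect_equal(nagelkerke_r2(glm(y ~ 1, family = binomial())), 0)
})
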