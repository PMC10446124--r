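#' Prior distribution for the measurement-error variance
#'
#' In a sensitivity analysis without validation data, uncertainty about the
#' measurement-error variance is expressed as a point, uniform, triangular,
#' or trapezoidal distribution over a plausible range, typically elicited
#' from literature or expert knowledge.
#'
#' @param shape `"point"`, `"uniform"`, `"triangular"`, or `"trapezoidal"`.
#' @param minimum,maximum Bounds of the support (variance units). For a point
#'   prior give `minimum` only.
#' @param mode Mode of a triangular prior.
#' @param mode_low,mode_high Plateau bounds of a trapezoidal prior.
#' @param n_draws Number of draws (>= 1, default 100).
#' @return An object of class `"tau_prior"`.
#' @export
#' @examples
#' tau_prior("triangular", 37, 59, mode = 48)
tau_prior <- function(shape = c("point", "uniform", "triangular", "trapezoidal"),
                      minimum, maximum = minimum, mode = NULL,
                      mode_low = NULL, mode_high = NULL, n_draws = 100) {
  shape <- match.arg(shape)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (minimum < 0) stop("variances must be non-negative", call. = FALSE)
  if (minimum > maximum) stop("minimum must not exceed maximum", call. = FALSE)
  if (shape == "triangular") {
    if (is.null(mode)) stop("triangular prior needs a mode", call. = FALSE)
    if (mode < minimum || mode > maximum)
      stop("mode must lie within [minimum, maximum]", call. = FALSE)
  }
  if (shape == "trapezoidal") {
    if (is.null(mode_low) || is.null(mode_high))
      stop("trapezoidal prior needs mode_low and mode_high", call. = FALSE)
    if (!(minimum <= mode_low && mode_low <= mode_high && mode_high <= maximum))
      stop("need minimum <= mode_low <= mode_high <= maximum", call. = FALSE)
  }
  structure(list(shape = shape, minimum = minimum, maximum = maximum,
                 mode = mode, mode_low = mode_low, mode_high = mode_high,
                 n_draws = as.integer(n_draws)),
            class = "tau_prior")
}

# closed-form inverse CDFs (Lash-style inverse-transform sampling)
quantile_tau_prior <- function(prior, u) {
  a <- prior$minimum; d <- prior$maximum
  switch(prior$shape,
    point = rep(a, length(u)),
    uniform = a + u * (d - a),
    triangular = {
      m <- prior$mode
      pc <- if (d > a) (m - a) / (d - a) else 0
      ifelse(u < pc,
             a + sqrt(u * (d - a) * (m - a)),
             d - sqrt((1 - u) * (d - a) * (d - m)))
    },
    trapezoidal = {
      b <- prior$mode_low; cc <- prior$mode_high
      h <- 2 / (d + cc - b - a)            # plateau density height
      p1 <- h * (b - a) / 2                # mass of the rising piece
      p2 <- p1 + h * (cc - b)              # mass up to the plateau end
      ifelse(u < p1,
             a + sqrt(2 * u * (b - a) / h),
             ifelse(u < p2,
                    b + (u - p1) / h,
                    d - sqrt(2 * (1 - u) * (d - cc) / h)))
    })
}

#' Sample measurement-error variances from a prior
#'
#' Inverse-CDF sampling of the prior's closed-form quantile function.
#'
#' @param prior A [tau_prior()].
#' @param seed Integer seed.
#' @return Numeric vector of `prior$n_draws` variances.
#' @export
sample_tau_prior <- function(prior, seed) {
  stopifnot(inherits(prior, "tau_prior"))
  set.seed(seed)
  quantile_tau_prior(prior, stats::runif(prior$n_draws))
}

#' Probabilistic sensitivity analysis for random measurement error
#'
#' For each tau2 drawn from the prior, corrects the naive estimate by
#' regression calibration or SIMEX with that tau2 treated as known, and
#' collects the corrected estimates. This operationalizes the five steps of a
#' quantitative bias analysis: quantify the error variance and its
#' uncertainty, specify its distribution, correct, visualize, conclude.
#' Draws for which the calibration factor is non-positive are recorded as
#' failed, never dropped silently.
#'
#' @param data A [study_data()].
#' @param prior A [tau_prior()].
#' @param method `"rc"` or `"simex"`.
#' @param seed Master seed (prior draws; per-draw SIMEX streams derive from it).
#' @param simex A [simex_config()] when `method = "simex"`.
#' @param bootstrap Optional [bootstrap_config()]; when supplied, a percentile
#'   CI and bootstrap SE are computed per draw (expensive but required for
#'   [probabilistic_bias_summary()]).
#' @return An object of class `"sensitivity_result"`: `$draws` is a
#'   data.frame (tau2, estimate, ci_low, ci_high, se, failed), `$summary`
#'   holds the median and range of the successful estimates, `$naive` the
#'   uncorrected reference fit.
#' @export
run_sensitivity <- function(data, prior, method = c("rc", "simex"), seed = 1,
                            simex = simex_config(), bootstrap = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(data, "study_data"), inherits(prior, "tau_prior"))
  tau2s <- sample_tau_prior(prior, seed)
  naive <- fit_naive(data)
  rows <- lapply(seq_along(tau2s), function(i) {
    em <- error_model(tau2s[i], source = "known")
    scfg <- simex; scfg$seed <- derive_seed(seed, i)
    res <- tryCatch({
      if (is.null(bootstrap)) {
        apply_method(data, method, em, FALSE, scfg)
      } else {
        bcfg <- bootstrap; bcfg$seed <- derive_seed(seed, i + prior$n_draws)
        bootstrap_ci(data, method, em, bcfg, scfg)
      }
    }, error = function(e) NULL)
    if (is.null(res))
      data.frame(tau2 = tau2s[i], estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, se = NA_real_, failed = TRUE)
    else
      data.frame(tau2 = tau2s[i], estimate = res$estimate,
                 ci_low = res$ci_low, ci_high = res$ci_high,
                 se = if (!is.null(res$diagnostics$boot_se))
                   res$diagnostics$boot_se else NA_real_,
                 failed = FALSE)
  })
  draws <- do.call(rbind, rows)
  ok <- draws$estimate[!draws$failed]
  if (!length(ok)) stop("all sensitivity draws failed", call. = FALSE)
  structure(list(draws = draws, method = method, prior = prior, naive = naive,
                 summary = list(median = stats::median(ok),
                                range = range(ok),
                                n_failed = sum(draws$failed))),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sensitivity analysis (%s), %d draws (%d failed)>\n",
              x$method, nrow(x$draws), s$n_failed))
  cat(sprintf("  naive estimate: %.4g\n", x$naive$estimate))
  cat(sprintf("  corrected estimates: median %.4g, range %.4g-%.4g\n",
              s$median, s$range[1], s$range[2]))
  invisible(x)
}

#' Probabilistic bias-analysis summary
#'
#' Propagates sampling uncertainty through the sensitivity draws: for each
#' draw, samples normal deviates with mean equal to the corrected point
#' estimate and standard deviation equal to its (bootstrap) standard error,
#' then pools all deviates and reports the median and 2.5/97.5 percentiles.
#'
#' @param result A [run_sensitivity()] result whose draws carry standard
#'   errors (run with a `bootstrap` config).
#' @param seed Integer seed.
#' @param n_per_draw Deviates per draw (default 1).
#' @return A list with the pooled `median`, `ci_low`, `ci_high` (2.5th and
#'   97.5th percentiles), and the pooled `samples`.
#' @export
probabilistic_bias_summary <- function(result, seed = 1, n_per_draw = 1) {
  stopifnot(inherits(result, "sensitivity_result"))
  d <- result$draws[!result$draws$failed, ]
  if (anyNA(d$se))
    stop("draws carry no standard errors; rerun run_sensitivity() with a bootstrap config",
         call. = FALSE)
  set.seed(seed)
  samples <- as.vector(vapply(seq_len(nrow(d)), function(i)
    stats::rnorm(n_per_draw, mean = d$estimate[i], sd = d$se[i]),
    numeric(n_per_draw)))
  qs <- stats::quantile(samples, c(0.025, 0.5, 0.975), names = FALSE)
  list(median = qs[2], ci_low = qs[1], ci_high = qs[3], samples = samples)
}

#' Plot a sensitivity analysis (estimate versus drawn error variance)
#'
#' Forest-style display: one corrected estimate (with its interval when
#' available) per drawn tau2, with the uncorrected estimate as a reference
#' band. Base graphics.
#'
#' @param x A `sensitivity_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sensitivity_result <- function(x, ...) {
  d <- x$draws[!x$draws$failed, ]
  has_ci <- !all(is.na(d$ci_low))
  ylim <- range(c(d$estimate, if (has_ci) c(d$ci_low, d$ci_high),
                  x$naive$estimate), na.rm = TRUE)
  graphics::plot(d$tau2, d$estimate, pch = 15, ylim = ylim,
                 xlab = expression(tau^2), ylab = "corrected estimate", ...)
  if (has_ci) graphics::segments(d$tau2, d$ci_low, d$tau2, d$ci_high,
                                 col = "grey60")
  graphics::abline(h = x$naive$estimate, lty = 2)
  invisible(x)
}
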