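#' Performance measures of a simulation scenario with Monte Carlo standard errors
#'
#' Aggregates repetition-level estimates into bias, percentage bias, mean
#' squared error, and (when interval bounds are supplied) coverage, each with
#' its Monte Carlo standard error:
#' MCSE(bias) = sd(estimates)/sqrt(R);
#' MCSE(MSE) = sqrt(sum(((est - truth)^2 - MSE)^2) / (R (R - 1)));
#' MCSE(coverage) = sqrt(cov (1 - cov) / R).
#'
#' @param estimates Numeric vector of per-repetition exposure estimates.
#' @param truth True value of the estimand (nonzero when percentage bias is
#'   requested).
#' @param ci_pairs Optional R x 2 matrix of per-repetition interval bounds.
#' @param scenario_label,method,family Labels carried into the summary row.
#' @return A one-row data.frame of class `"performance_summary"`.
#' @export
#' @examples
#' compute_metrics(c(0.1, 0.3), truth = 0.2) # bias 0, mse 0.01
compute_metrics <- function(estimates, truth, ci_pairs = NULL,
                            scenario_label = NA_character_,
                            method = NA_character_, family = NA_character_) {
  estimates <- estimates[!is.na(estimates)]
  R <- length(estimates)
  if (R < 2) stop("at least 2 repetitions are required", call. = FALSE)
  if (!is.finite(truth)) stop("truth must be finite", call. = FALSE)
  if (truth == 0)
    stop("percentage bias is undefined for truth = 0", call. = FALSE)
  bias <- mean(estimates) - truth
  sqerr <- (estimates - truth)^2
  mse <- mean(sqerr)
  mcse_bias <- stats::sd(estimates) / sqrt(R)
  mcse_mse <- sqrt(sum((sqerr - mse)^2) / (R * (R - 1)))
  if (is.null(ci_pairs)) {
    coverage <- NA_real_; mcse_cov <- NA_real_
  } else {
    ci_pairs <- as.matrix(ci_pairs)
    ok <- stats::complete.cases(ci_pairs)
    covered <- ci_pairs[ok, 1] <= truth & truth <= ci_pairs[ok, 2]
    coverage <- mean(covered)
    mcse_cov <- sqrt(coverage * (1 - coverage) / sum(ok))
  }
  structure(
    data.frame(scenario_label = scenario_label, family = family,
               method = method, n_reps = R, bias = bias,
               pct_bias = 100 * bias / truth, mse = mse, coverage = coverage,
               mcse_bias = mcse_bias,
               mcse_pct_bias = 100 * mcse_bias / abs(truth),
               mcse_mse = mcse_mse, mcse_coverage = mcse_cov,
               stringsAsFactors = FALSE),
    class = c("performance_summary", "data.frame")
  )
}

#' Run the Monte Carlo simulation for one scenario
#'
#' Generates `n_reps` datasets from the scenario, applies each requested
#' method, and summarizes performance against the scenario's true conditional
#' effect. Per-repetition seeds are derived deterministically from the master
#' seed so any single repetition can be reproduced in isolation. Coverage is
#' computed only when a [bootstrap_config()] is supplied, because bootstrap
#' inside Monte Carlo dominates the cost of a run.
#'
#' @param scenario A scenario from [linear_scenario()], [logistic_scenario()]
#'   or [scenario_grid()].
#' @param methods Subset of `c("naive", "rc", "simex")`.
#' @param n_reps Number of repetitions (>= 2).
#' @param seed Master seed.
#' @param simex A [simex_config()] (used when `"simex"` is requested).
#' @param bootstrap Optional [bootstrap_config()]; enables coverage.
#' @param keep_estimates Attach the per-repetition estimates for audit
#'   (default `TRUE`).
#' @return A data.frame with one `performance_summary` row per method;
#'   attribute `"estimates"` holds the repetition-level estimates, and
#'   attribute `"n_failed"` the failed-repetition count per method.
#' @export
run_scenario <- function(scenario, methods = c("naive", "rc", "simex"),
                         n_reps = 1000, seed = 1, simex = simex_config(),
                         bootstrap = NULL, keep_estimates = TRUE) {
  stopifnot(inherits(scenario, "me_scenario"), n_reps >= 2)
  methods <- match.arg(methods, c("naive", "rc", "simex"), several.ok = TRUE)
  est <- matrix(NA_real_, nrow = n_reps, ncol = length(methods),
                dimnames = list(NULL, methods))
  ci <- if (!is.null(bootstrap))
    lapply(stats::setNames(methods, methods),
           function(m) matrix(NA_real_, n_reps, 2))
  # per-repetition seed table drawn from the master seed: seeds in arithmetic
  # progression are avoided deliberately (they can correlate generated
  # datasets across repetitions); any repetition is reproducible by
  # regenerating this table from the master seed
  S <- rep_seed_table(seed, n_reps)
  for (r in seq_len(n_reps)) {
    data <- generate_study(scenario, S[r, 1L])
    for (m in methods) {
      res <- tryCatch({
        if (is.null(bootstrap)) {
          scfg <- simex; scfg$seed <- S[r, 2L]
          apply_method(data, m, NULL, TRUE, scfg)
        } else {
          bcfg <- bootstrap; bcfg$seed <- S[r, 3L]
          scfg <- simex; scfg$seed <- S[r, 2L]
          bootstrap_ci(data, m, NULL, bcfg, scfg)
        }
      }, error = function(e) NULL)
      if (!is.null(res)) {
        est[r, m] <- res$estimate
        if (!is.null(bootstrap)) ci[[m]][r, ] <- c(res$ci_low, res$ci_high)
      }
    }
  }
  out <- do.call(rbind, lapply(methods, function(m) {
    compute_metrics(est[, m], truth = scenario$beta_true,
                    ci_pairs = if (!is.null(bootstrap)) ci[[m]][!is.na(est[, m]), , drop = FALSE],
                    scenario_label = scenario$label, method = m,
                    family = scenario$family)
  }))
  attr(out, "n_failed") <- colSums(is.na(est))
  if (keep_estimates) attr(out, "estimates") <- est
  out
}

#' Study-level summary of per-scenario performance
#'
#' Medians and interquartile ranges of percentage bias, MSE, and coverage per
#' method, pooled over all supplied scenarios and, when more than one family
#' is present, also per family. Quantiles use linear interpolation between
#' order statistics (`stats::quantile()` type 7).
#'
#' @param per_scenario A data.frame of `performance_summary` rows (e.g.,
#'   `rbind()` of [run_scenario()] outputs) or a list of them.
#' @return A data.frame with one row per method (and per family when pooled
#'   over several), with `*_median`, `*_q1`, `*_q3` columns.
#' @export
summarize_study <- function(per_scenario) {
  if (is.list(per_scenario) && !is.data.frame(per_scenario))
    per_scenario <- do.call(rbind, per_scenario)
  stopifnot(is.data.frame(per_scenario), nrow(per_scenario) >= 1)
  q <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  }
  one <- function(df, scope) {
    do.call(rbind, lapply(split(df, df$method), function(d) {
      pb <- q(d$pct_bias); ms <- q(d$mse); cv <- q(d$coverage)
      data.frame(scope = scope, method = d$method[1], n_scenarios = nrow(d),
                 pct_bias_median = pb[1], pct_bias_q1 = pb[2], pct_bias_q3 = pb[3],
                 mse_median = ms[1], mse_q1 = ms[2], mse_q3 = ms[3],
                 coverage_median = cv[1], coverage_q1 = cv[2], coverage_q3 = cv[3],
                 stringsAsFactors = FALSE)
    }))
  }
  out <- one(per_scenario, "pooled")
  fams <- unique(per_scenario$family)
  if (length(fams) > 1)
    for (f in fams) out <- rbind(out, one(per_scenario[per_scenario$family == f, ], f))
  rownames(out) <- NULL
  out
}
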