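#' Define a linear-regression simulation scenario
#'
#' A scenario parameterizes the blood-pressure/creatinine data-generating
#' mechanism used throughout the simulation study: Age ~ N(32, 25),
#' BP | Age ~ N(120 + gamma * Age, 50), error-prone replicates
#' BP* | BP ~ N(BP, tau2), and Creatinine | BP, Age ~
#' N(30 + 0.2 * BP + 0.2 * Age, sigma2). The true conditional effect of the
#' exposure on the outcome is 0.2 (creatinine units per mmHg).
#'
#' @param tau2 Measurement-error variance of the error-prone blood pressure
#'   replicates (mmHg^2). Must be >= 0.
#' @param n Number of observations in the main study (>= 2).
#' @param k Number of replicate error-prone measurements (integer >= 2).
#' @param sigma2 Residual variance of the outcome model (> 0).
#' @param gamma Effect of age on blood pressure (covariate dependency).
#' @param label Scenario name used in reports.
#' @return An object of class `c("linear_scenario", "me_scenario")`.
#' @seealso [logistic_scenario()], [scenario_grid()], [generate_linear()]
#' @export
#' @examples
#' sc <- linear_scenario() # the base scenario
#' reliability(sc)         # 0.625
linear_scenario <- function(tau2 = 30, n = 500, k = 3, sigma2 = 100,
                            gamma = 0, label = "base") {
  stopifnot(is.numeric(tau2), length(tau2) == 1L, tau2 >= 0)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("invalid scenario: n must be >= 2", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("invalid scenario: k must be an integer >= 2", call. = FALSE)
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("invalid scenario: sigma2 must be > 0", call. = FALSE)
  structure(
    list(family = "linear", tau2 = tau2, n = as.integer(n), k = as.integer(k),
         sigma2 = sigma2, gamma = gamma, beta_true = 0.2, label = label),
    class = c("linear_scenario", "me_scenario")
  )
}

#' Define a logistic-regression simulation scenario
#'
#' Parameterizes the sodium-intake/hypertension mechanism: Age ~ U(18, 80),
#' Na | Age ~ N(4 + gamma * Age, 1), error-prone replicates
#' Na* | Na ~ N(Na, tau2), and Hypertension | Na, Age ~
#' Bernoulli(expit(-7 + 0.1 * Na + phi * Age)). The true conditional
#' log-odds effect of sodium intake is 0.1 per gram.
#'
#' @param tau2 Measurement-error variance of the error-prone sodium intake (g^2).
#' @param n Number of observations (>= 2).
#' @param k Number of replicate measurements (integer >= 2).
#' @param phi Effect of age on the hypertension log-odds (given sodium intake).
#' @param gamma Effect of age on sodium intake.
#' @param label Scenario name.
#' @return An object of class `c("logistic_scenario", "me_scenario")`.
#' @export
logistic_scenario <- function(tau2 = 2, n = 4000, k = 2, phi = 0.1,
                              gamma = 0, label = "base") {
  stopifnot(is.numeric(tau2), length(tau2) == 1L, tau2 >= 0)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("invalid scenario: n must be >= 2", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("invalid scenario: k must be an integer >= 2", call. = FALSE)
  structure(
    list(family = "logistic", tau2 = tau2, n = as.integer(n), k = as.integer(k),
         phi = phi, gamma = gamma, beta_true = 0.1, label = label),
    class = c("logistic_scenario", "me_scenario")
  )
}

#' @export
print.me_scenario <- function(x, ...) {
  cat(sprintf("<%s scenario '%s'>\n", x$family, x$label))
  flds <- setdiff(names(x), c("family", "label"))
  cat(paste(sprintf("  %s = %g", flds, unlist(x[flds])), collapse = "\n"), "\n")
  invisible(x)
}

# variance of Age in the logistic mechanism, Var(Uniform(18, 80))
var_age_uniform <- (80 - 18)^2 / 12

#' Attenuation factor (regression dilution) of the naive estimator
#'
#' Multiplicative bias of the naive exposure coefficient under classical
#' measurement error: the variance of the true exposure given the covariates
#' divided by the same quantity plus the measurement-error variance. In
#' multivariable models this conditional form, not the marginal reliability,
#' governs the bias.
#'
#' @param var_x_given_c Variance of the true exposure given the covariates (> 0).
#' @param tau2 Measurement-error variance (>= 0).
#' @return The attenuation factor in (0, 1].
#' @export
#' @examples
#' attenuation_factor(50, 30) # 0.625
attenuation_factor <- function(var_x_given_c, tau2) {
  if (!is.numeric(var_x_given_c) || any(var_x_given_c <= 0))
    stop("var_x_given_c must be > 0", call. = FALSE)
  if (!is.numeric(tau2) || any(tau2 < 0))
    stop("tau2 must be >= 0", call. = FALSE)
  var_x_given_c / (var_x_given_c + tau2)
}

#' Reliability of the error-prone exposure measurement
#'
#' Marginal variance of the true exposure divided by the marginal variance of
#' the error-prone exposure. For the linear mechanism this is
#' (25 gamma^2 + 50) / (25 gamma^2 + 50 + tau2); for the logistic mechanism
#' (gamma^2 (80-18)^2/12 + 1) / (gamma^2 (80-18)^2/12 + 1 + tau2).
#' Reliability equals the attenuation factor only when the exposure is
#' independent of the covariates (gamma = 0).
#'
#' @param scenario A [linear_scenario()] or [logistic_scenario()].
#' @return Reliability in (0, 1].
#' @export
reliability <- function(scenario) {
  stopifnot(inherits(scenario, "me_scenario"))
  var_x <- true_exposure_variance(scenario)
  var_x / (var_x + scenario$tau2)
}

# marginal variance of the true exposure implied by a scenario
true_exposure_variance <- function(scenario) {
  if (scenario$family == "linear") 25 * scenario$gamma^2 + 50
  else scenario$gamma^2 * var_age_uniform + 1
}

# variance of the true exposure given the covariate (age)
conditional_exposure_variance <- function(scenario) {
  if (scenario$family == "linear") 50 else 1
}

#' Crude (unadjusted) effect of the exposure in the linear mechanism
#'
#' The population coefficient of an outcome model that omits age:
#' 0.2 + 5 gamma / (25 gamma^2 + 50). Equal to the conditional effect 0.2
#' when gamma = 0 (exposure independent of the covariate).
#'
#' @param scenario A [linear_scenario()].
#' @return The crude regression coefficient.
#' @export
crude_effect <- function(scenario) {
  stopifnot(inherits(scenario, "linear_scenario"))
  0.2 + 5 * scenario$gamma / (25 * scenario$gamma^2 + 50)
}

#' Coefficient of determination of the linear outcome model
#'
#' Two conventions are reported. `"dgm"` derives the explained variance from
#' the generating coefficients (0.2, 0.2): Var(0.2 BP + 0.2 Age) =
#' 0.04 (25 gamma^2 + 50) + 0.04 * 25 + 2 * 0.04 * 25 gamma. `"footnote"`
#' uses the fixed explained variance 0.4 * 50 + 10 = 30 so that R^2 =
#' 1 - sigma2 / (30 + sigma2). The two disagree (at gamma = 0 the DGM
#' convention gives explained variance 3, hence R^2 = 0.03 at sigma2 = 100);
#' both are exposed so scenarios can be labeled either way.
#'
#' @param scenario A [linear_scenario()].
#' @param convention `"dgm"` (default) or `"footnote"`.
#' @return R-squared in (0, 1).
#' @export
outcome_r_squared <- function(scenario, convention = c("dgm", "footnote")) {
  stopifnot(inherits(scenario, "linear_scenario"))
  convention <- match.arg(convention)
  explained <- switch(convention,
    dgm = 0.04 * (25 * scenario$gamma^2 + 50) + 0.04 * 25 +
      2 * 0.04 * 25 * scenario$gamma,
    footnote = 0.4 * 50 + 10
  )
  explained / (explained + scenario$sigma2)
}

#' The published one-factor-at-a-time scenario grid
#'
#' Returns the full simulation grid for one outcome family: the base scenario
#' plus variations in measurement-error variance (reliability), sample size,
#' number of replicates, residual variance / age effect (R-squared), and
#' covariate dependency, each changing exactly one parameter of the base.
#'
#' @param family `"linear"` or `"logistic"`.
#' @return A named list of 22 scenarios.
#' @export
#' @examples
#' length(scenario_grid("linear")) # 22
scenario_grid <- function(family = c("linear", "logistic")) {
  family <- match.arg(family)
  grid <- list()
  add <- function(sc) grid[[sc$label]] <<- sc
  if (family == "linear") {
    add(linear_scenario())
    for (t2 in c(200, 100, 50, 25, 20, 15, 10, 5))
      add(linear_scenario(tau2 = t2, label = sprintf("reliability_tau2_%g", t2)))
    for (n in c(125, 250, 1000, 10000))
      add(linear_scenario(n = n, label = sprintf("sample_size_%d", n)))
    for (k in c(2, 5, 10))
      add(linear_scenario(k = k, label = sprintf("replicates_%d", k)))
    for (s2 in c(20, 5, 10))
      add(linear_scenario(sigma2 = s2, label = sprintf("r_squared_sigma2_%g", s2)))
    for (g in c(1, 4, 8))
      add(linear_scenario(gamma = g, label = sprintf("covariate_dependency_%g", g)))
  } else {
    add(logistic_scenario())
    for (t2 in c(20, 10, 4, 1.5, 1, 0.5, 0.25, 0.1))
      add(logistic_scenario(tau2 = t2, label = sprintf("reliability_tau2_%g", t2)))
    for (n in c(500, 1000, 2000, 10000))
      add(logistic_scenario(n = n, label = sprintf("sample_size_%d", n)))
    for (k in c(3, 5, 10))
      add(logistic_scenario(k = k, label = sprintf("replicates_%d", k)))
    for (p in c(0.06, 0.08, 0.2))
      add(logistic_scenario(phi = p, label = sprintf("r_squared_phi_%g", p)))
    for (g in c(0.01, 0.1, 0.2))
      add(logistic_scenario(gamma = g, label = sprintf("covariate_dependency_%g", g)))
  }
  grid
}
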