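#' Generate a dataset from the linear (blood pressure/creatinine) mechanism
#'
#' Draws Age ~ N(32, 25), true blood pressure BP | Age ~ N(120 + gamma Age, 50),
#' k mutually independent error-prone replicates BP* | BP ~ N(BP, tau2), and
#' the outcome Creatinine | BP, Age ~ N(30 + 0.2 BP + 0.2 Age, sigma2).
#' Replicates carry classical (random) error: independent of the truth and of
#' each other given the truth.
#'
#' @param scenario A [linear_scenario()].
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @return A [study_data()] with the age covariate and the true exposure retained.
#' @export
#' @examples
#' d <- generate_linear(linear_scenario(), seed = 1)
#' d
generate_linear <- function(scenario, seed) {
  stopifnot(inherits(scenario, "linear_scenario"))
  set.seed(seed)
  n <- scenario$n; k <- scenario$k
  age <- stats::rnorm(n, mean = 32, sd = 5)
  bp <- stats::rnorm(n, mean = 120 + scenario$gamma * age, sd = sqrt(50))
  W <- matrix(stats::rnorm(n * k, mean = bp, sd = sqrt(scenario$tau2)),
              nrow = n, ncol = k)
  colnames(W) <- paste0("w", seq_len(k))
  y <- stats::rnorm(n, mean = 30 + 0.2 * bp + 0.2 * age,
                    sd = sqrt(scenario$sigma2))
  study_data(outcome = y, exposure_replicates = W,
             covariates = matrix(age, ncol = 1, dimnames = list(NULL, "age")),
             family = "linear", true_exposure = bp)
}

#' Generate a dataset from the logistic (sodium/hypertension) mechanism
#'
#' Draws Age ~ U(18, 80), true sodium intake Na | Age ~ N(4 + gamma Age, 1),
#' k independent error-prone replicates Na* | Na ~ N(Na, tau2), and a
#' Bernoulli hypertension outcome with success probability
#' expit(-7 + 0.1 Na + phi Age).
#'
#' @param scenario A [logistic_scenario()].
#' @param seed Integer seed.
#' @return A [study_data()] with the age covariate and true exposure retained.
#' @export
generate_logistic <- function(scenario, seed) {
  stopifnot(inherits(scenario, "logistic_scenario"))
  set.seed(seed)
  n <- scenario$n; k <- scenario$k
  age <- stats::runif(n, 18, 80)
  na <- stats::rnorm(n, mean = 4 + scenario$gamma * age, sd = 1)
  W <- matrix(stats::rnorm(n * k, mean = na, sd = sqrt(scenario$tau2)),
              nrow = n, ncol = k)
  colnames(W) <- paste0("w", seq_len(k))
  p <- stats::plogis(-7 + 0.1 * na + scenario$phi * age)
  y <- stats::rbinom(n, 1, p)
  study_data(outcome = y, exposure_replicates = W,
             covariates = matrix(age, ncol = 1, dimnames = list(NULL, "age")),
             family = "logistic", true_exposure = na)
}

#' Generate a dataset from any scenario
#'
#' Dispatches to [generate_linear()] or [generate_logistic()].
#'
#' @param scenario A scenario object.
#' @param seed Integer seed.
#' @return A [study_data()].
#' @export
generate_study <- function(scenario, seed) {
  if (inherits(scenario, "linear_scenario")) generate_linear(scenario, seed)
  else if (inherits(scenario, "logistic_scenario")) generate_logistic(scenario, seed)
  else stop("unknown scenario family", call. = FALSE)
}

#' Write a study dataset to CSV with a sidecar provenance file
#'
#' Columns are `outcome`, `w1..wk`, the covariates, and optionally `x_true`.
#' When a scenario and seed are supplied, a JSON sidecar (`<path>.json`)
#' records them so the dataset can be regenerated.
#'
#' @param data A [study_data()].
#' @param path Output CSV path.
#' @param scenario Optional generating scenario, recorded in the sidecar.
#' @param seed Optional generating seed, recorded in the sidecar.
#' @param include_true Write the true exposure column (synthetic data only).
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(data, path, scenario = NULL, seed = NULL,
                            include_true = FALSE) {
  stopifnot(inherits(data, "study_data"))
  df <- data.frame(outcome = data$outcome, data$exposure_replicates,
                   check.names = FALSE)
  if (ncol(data$covariates) > 0) df <- cbind(df, data$covariates)
  if (include_true) {
    if (is.null(data$true_exposure))
      stop("no true exposure retained in this dataset", call. = FALSE)
    df$x_true <- data$true_exposure
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(scenario) || !is.null(seed)) {
    sidecar <- list(family = data$family, seed = seed,
                    scenario = if (!is.null(scenario)) unclass(scenario))
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
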