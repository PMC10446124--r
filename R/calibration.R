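#' Describe the assumed measurement-error model
#'
#' Holds the classical measurement-error variance tau2 and its provenance:
#' estimated from replicate measurements, or supplied as known (e.g., from
#' external data or expert knowledge in a sensitivity analysis).
#'
#' @param tau2 Measurement-error variance (>= 0), in squared exposure units.
#' @param source `"known"` or `"replicates"`.
#' @param tau2_se Optional standard error when tau2 was estimated.
#' @return An object of class `"error_model"`.
#' @export
error_model <- function(tau2, source = c("known", "replicates"), tau2_se = NULL) {
  source <- match.arg(source)
  if (!is.numeric(tau2) || length(tau2) != 1L || tau2 < 0)
    stop("tau2 must be a single non-negative number", call. = FALSE)
  structure(list(tau2 = tau2, source = source, tau2_se = tau2_se),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model: tau2 = %g (%s)>\n", x$tau2, x$source))
  invisible(x)
}

# common container for naive / RC / SIMEX results
correction_result <- function(estimate, method, n_used, ci_low = NA_real_,
                              ci_high = NA_real_, diagnostics = list()) {
  if (!is.na(ci_low) && !is.na(ci_high) &&
      !(ci_low <= estimate && estimate <= ci_high))
    stop("confidence interval does not contain the estimate", call. = FALSE)
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 method = method, diagnostics = diagnostics,
                 n_used = as.integer(n_used)),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (%.4g; %.4g)", x$ci_low, x$ci_high)
  cat(sprintf("%s exposure estimate: %.4g%s  [n = %d]\n",
              x$method, x$estimate, ci, x$n_used))
  invisible(x)
}

# design matrix for the outcome model: intercept, first replicate, covariates
naive_design <- function(data) {
  cbind(`(Intercept)` = 1, exposure = data$exposure_replicates[, 1L],
        data$covariates)
}

# vectorized pooled within-row variance; fast path for resampling loops
tau2_hat_fast <- function(W) mean(rowSums((W - rowMeans(W))^2) / (ncol(W) - 1L))

# residual variance of the first replicate given the covariates, matrix form
cond_var_fast <- function(w, C) {
  X <- cbind(1, C)
  r <- stats::.lm.fit(X, w)$residuals
  sum(r^2) / (length(w) - ncol(X))
}

# exposure coefficient only; fast path used inside SIMEX/bootstrap loops
fit_exposure_coef <- function(y, X, family) {
  if (family == "linear") {
    stats::.lm.fit(X, y)$coefficients[2L]
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(maxit = 50))
    )
    if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
    fit$coefficients[2L]
  }
}

#' Naive (uncorrected) outcome-model fit
#'
#' Fits the outcome model using the first error-prone replicate only, ignoring
#' measurement error: ordinary least squares for the linear family, maximum
#' likelihood logistic regression for the logistic family. This is the
#' estimator whose attenuation the correction methods undo.
#'
#' @param data A [study_data()].
#' @param ci_level Wald confidence level (default 0.95).
#' @return A `correction_result` with method `"naive"`; `diagnostics$se` holds
#'   the model-based standard error.
#' @export
fit_naive <- function(data, ci_level = 0.95) {
  stopifnot(inherits(data, "study_data"))
  df <- data.frame(.y = data$outcome,
                   .w = data$exposure_replicates[, 1L])
  if (ncol(data$covariates) > 0) df <- cbind(df, data$covariates)
  rhs <- paste(c(".w", colnames(data$covariates)), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  if (data$family == "linear") {
    fit <- stats::lm(fml, data = df)
  } else {
    if (length(unique(data$outcome)) < 2L)
      stop("fit failure: logistic outcome has a single class", call. = FALSE)
    fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
    if (!fit$converged)
      stop("fit failure: logistic model did not converge (possible separation)",
           call. = FALSE)
  }
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("fit failure: collinear design matrix", call. = FALSE)
  est <- unname(co[".w"])
  se <- sqrt(diag(stats::vcov(fit)))[[".w"]]
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  correction_result(est, method = "naive", n_used = n_obs(data),
                    ci_low = est - z * se, ci_high = est + z * se,
                    diagnostics = list(se = se, ci_type = "wald"))
}

#' Estimate the measurement-error variance from replicate measurements
#'
#' Pooled within-individual variance: the sample variance (denominator k - 1)
#' of each individual's k replicates, averaged over individuals. Unbiased for
#' tau2 under classical error with exchangeable replicates.
#'
#' @param data A [study_data()] with k >= 2 replicates.
#' @return An [error_model()] with `source = "replicates"`; the standard error
#'   of the mean within-individual variance is attached.
#' @export
#' @examples
#' d <- study_data(c(0, 0, 0), rbind(c(1, 3), c(2, 2), c(0, 4)))
#' estimate_tau2_replicates(d)$tau2 # 10/3
estimate_tau2_replicates <- function(data) {
  stopifnot(inherits(data, "study_data"))
  W <- data$exposure_replicates
  if (ncol(W) < 2L)
    stop("insufficient replicates: k >= 2 required to estimate tau2",
         call. = FALSE)
  wi <- rowSums((W - rowMeans(W))^2) / (ncol(W) - 1L)
  error_model(mean(wi), source = "replicates",
              tau2_se = stats::sd(wi) / sqrt(length(wi)))
}

#' Variance of the error-prone exposure given the covariates
#'
#' Residual variance from an ordinary least-squares regression of the first
#' replicate on the covariates (intercept included), with denominator
#' n - (c + 1). With no covariates this is the sample variance of the
#' replicate. This is the denominator quantity of the attenuation factor.
#'
#' @param data A [study_data()].
#' @return A single variance.
#' @export
conditional_variance <- function(data) {
  stopifnot(inherits(data, "study_data"))
  w <- data$exposure_replicates[, 1L]
  X <- cbind(1, data$covariates)
  n <- length(w)
  if (n <= ncol(X))
    stop("too few observations for the calibration regression", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient covariate matrix", call. = FALSE)
  fit <- stats::lm.fit(X, w)
  sum(fit$residuals^2) / (n - ncol(X))
}

#' Regression-calibration correction
#'
#' Divides the naive exposure coefficient by the estimated attenuation factor:
#' the estimate is multiplied by v / (v - tau2) where v is the variance of the
#' error-prone exposure given the covariates ([conditional_variance()]). The
#' same ratio is applied to the linear slope and, following Rosner-style
#' calibration, to the logistic log-odds coefficient (approximate for
#' logistic models with a non-small exposure effect or error variance).
#' Covariate coefficients are not corrected.
#'
#' @param data A [study_data()].
#' @param error_model An [error_model()]; if `NULL`, tau2 is estimated from
#'   the replicates via [estimate_tau2_replicates()].
#' @param naive Optional precomputed [fit_naive()] result (avoids refitting).
#' @return A `correction_result` with method `"rc"`; diagnostics record the
#'   attenuation factor `lambda`, the conditional variance, and tau2.
#' @export
rc_correct <- function(data, error_model = NULL, naive = NULL) {
  stopifnot(inherits(data, "study_data"))
  if (is.null(error_model)) error_model <- estimate_tau2_replicates(data)
  stopifnot(inherits(error_model, "error_model"))
  if (is.null(naive)) naive <- fit_naive(data)
  v <- conditional_variance(data)
  denom <- v - error_model$tau2
  if (denom <= 0)
    stop(sprintf(paste0("non-positive calibration factor: conditional variance ",
                        "%.6g <= tau2 %.6g; regression calibration is unstable ",
                        "when the correction factor is close to null"),
                 v, error_model$tau2), call. = FALSE)
  lambda <- denom / v
  correction_result(naive$estimate / lambda, method = "rc", n_used = n_obs(data),
                    diagnostics = list(lambda = lambda, conditional_variance = v,
                                       tau2 = error_model$tau2,
                                       tau2_source = error_model$source,
                                       naive_estimate = naive$estimate))
}

#' Nagelkerke pseudo R-squared of a fitted logistic model
#'
#' Rescaled likelihood-ratio R-squared analogue:
#' (1 - exp((D - D0)/n)) / (1 - exp(-D0/n)) with D the model deviance and D0
#' the null deviance.
#'
#' @param fit A fitted [stats::glm()] binomial model.
#' @return Pseudo R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  num <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  den <- 1 - exp(-fit$null.deviance / n)
  num / den
}
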