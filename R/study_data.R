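#' Construct a study dataset for measurement-error analysis
#'
#' Bundles one analysis dataset: an outcome, an n x k matrix of error-prone
#' exposure replicates, optional covariates, and (for synthetic data only)
#' the true exposure, used by oracle checks. No missingness is handled.
#'
#' @param outcome Numeric vector of length n (0/1 for the logistic family).
#' @param exposure_replicates Numeric n x k matrix (k >= 1) of error-prone
#'   measurements of the same exposure; columns are exchangeable replicates.
#' @param covariates Numeric n x c matrix or data.frame (c >= 0).
#' @param family `"linear"` or `"logistic"`.
#' @param true_exposure Optional numeric vector of length n.
#' @return An object of class `"study_data"`.
#' @export
study_data <- function(outcome, exposure_replicates, covariates = NULL,
                       family = c("linear", "logistic"), true_exposure = NULL) {
  family <- match.arg(family)
  W <- as.matrix(exposure_replicates)
  n <- length(outcome)
  if (nrow(W) != n) stop("exposure_replicates must have one row per outcome",
                         call. = FALSE)
  if (ncol(W) < 1L) stop("at least one replicate column is required", call. = FALSE)
  if (is.null(covariates)) {
    C <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariates must have one row per outcome", call. = FALSE)
  }
  if (anyNA(outcome) || anyNA(W) || anyNA(C))
    stop("missing values are not supported", call. = FALSE)
  if (!is.numeric(outcome) || !is.numeric(W) || (ncol(C) > 0 && !is.numeric(C)))
    stop("outcome, replicates and covariates must be numeric", call. = FALSE)
  if (family == "logistic" && !all(outcome %in% c(0, 1)))
    stop("logistic outcome must contain only 0 and 1", call. = FALSE)
  if (!is.null(true_exposure) && length(true_exposure) != n)
    stop("true_exposure must have length n", call. = FALSE)
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  if (ncol(C) > 0 && is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
  structure(
    list(outcome = as.numeric(outcome), exposure_replicates = W,
         covariates = C, true_exposure = true_exposure, family = family),
    class = "study_data"
  )
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("<study_data: %s outcome, n = %d, k = %d replicates, %d covariate(s)%s>\n",
              x$family, n_obs(x), n_replicates(x), ncol(x$covariates),
              if (is.null(x$true_exposure)) "" else ", true exposure retained"))
  invisible(x)
}

#' @rdname study_data
#' @param x A `study_data` object.
#' @export
n_obs <- function(x) length(x$outcome)

#' @rdname study_data
#' @export
n_replicates <- function(x) ncol(x$exposure_replicates)

# row subset preserving replicates/covariates together (bootstrap resampling)
subset_rows <- function(data, idx) {
  study_data(
    outcome = data$outcome[idx],
    exposure_replicates = data$exposure_replicates[idx, , drop = FALSE],
    covariates = if (ncol(data$covariates) > 0)
      data$covariates[idx, , drop = FALSE] else NULL,
    family = data$family,
    true_exposure = if (!is.null(data$true_exposure)) data$true_exposure[idx]
  )
}
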