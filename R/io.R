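#' Read a study dataset from CSV
#'
#' Columns are assigned roles by name: one outcome, one or more error-prone
#' exposure replicates, zero or more covariates. Cells must be numeric and
#' complete; violations are reported with row numbers.
#'
#' @param path CSV file path.
#' @param outcome Name of the outcome column.
#' @param replicates Character vector of replicate column names (order gives
#'   w1..wk; the first is the designated single measurement for naive fits).
#' @param covariates Character vector of covariate column names (may be empty).
#' @param family `"linear"` or `"logistic"`.
#' @return A [study_data()].
#' @export
load_study_csv <- function(path, outcome, replicates, covariates = character(),
                           family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(outcome, replicates, covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop(sprintf("column '%s' is not numeric (first offending row: %d)",
                   col, which(is.na(suppressWarnings(as.numeric(v))))[1]),
           call. = FALSE)
    if (anyNA(v))
      stop(sprintf("column '%s' has missing values (rows %s)",
                   col, paste(utils::head(which(is.na(v)), 5), collapse = ", ")),
           call. = FALSE)
  }
  W <- as.matrix(df[replicates]); colnames(W) <- paste0("w", seq_along(replicates))
  C <- if (length(covariates)) as.matrix(df[covariates]) else NULL
  study_data(outcome = df[[outcome]], exposure_replicates = W,
             covariates = C, family = family)
}

# CorrectionResult -> JSON-ready list
result_to_list <- function(res) {
  list(estimate = res$estimate, ci_low = res$ci_low, ci_high = res$ci_high,
       method = res$method, n_used = res$n_used,
       diagnostics = lapply(res$diagnostics, function(d)
         if (is.numeric(d) && !is.null(names(d))) as.list(d) else d))
}

#' Write a correction result as JSON with a one-line summary
#'
#' @param res A `correction_result`.
#' @param path Output JSON path.
#' @param quiet Suppress the one-line console summary.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(res, path, quiet = FALSE) {
  stopifnot(inherits(res, "correction_result"))
  jsonlite::write_json(result_to_list(res), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  if (!quiet) print(res)
  invisible(path)
}
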