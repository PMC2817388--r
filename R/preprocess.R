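# Preprocessing: replicate averaging, median dichotomization, single-value
# (mode) imputation, and outcome dichotomization at 450 cells/uL.

#' Average replicate acquisitions
#'
#' Per-subject arithmetic mean of up to four independent acquisitions,
#' using the observed (non-missing) acquisitions only.  A subject with no
#' observed acquisition gets a missing mean.
#'
#' @param acquisitions a list of per-acquisition numeric vectors (or
#'   matrices with identical dimensions), or a matrix whose columns are
#'   acquisitions of a single quantity.
#' @return Elementwise mean with the same shape as one acquisition.
#' @examples
#' average_replicates(list(c(1, 5), c(2, 5), c(3, 5), c(NA, 5)))  # 2, 5
#' @export
average_replicates <- function(acquisitions) {
  if (is.matrix(acquisitions))
    acquisitions <- lapply(asplit(acquisitions, 2L), as.vector)
  if (!is.list(acquisitions) || length(acquisitions) < 1L || length(acquisitions) > 4L)
    stop_ft("acquisitions must be a list of 1-4 replicates", class = "flowtrees_input_error")
  tot <- Reduce(`+`, lapply(acquisitions, function(a) ifelse(is.na(a), 0, a)))
  cnt <- Reduce(`+`, lapply(acquisitions, function(a) !is.na(a)))
  out <- tot / cnt            # 0/0 -> NaN where nothing observed
  out[cnt == 0] <- NA
  out
}

#' Dichotomize a column at its observed median
#'
#' An observed value maps to 1 if strictly greater than the median of the
#' observed values, 0 otherwise (ties at the median map to 0); missing stays
#' missing.  The median used is returned as an attribute.
#'
#' @param column numeric vector, possibly with `NA`.
#' @return Integer 0/1 vector with `NA` preserved and attribute `"median"`.
#' @examples
#' dichotomize_at_median(c(1, 2, 3, 4, 5))  # 0 0 0 1 1, median 3
#' @export
dichotomize_at_median <- function(column) {
  obs <- column[!is.na(column)]
  if (length(obs) == 0L)
    stop_ft("cannot dichotomize an all-missing column", class = "flowtrees_empty_column_error")
  m <- median(obs)
  out <- as.integer(column > m)
  attr(out, "median") <- m
  out
}

#' Impute missing binary values with the observed mode
#'
#' Each missing cell is replaced by the most common observed value; an exact
#' tie between 0 and 1 imputes 0.
#'
#' @param column 0/1 vector with possible `NA`.
#' @return Integer 0/1 vector; attribute `"imputed"` holds the imputed
#'   positions (empty if none).
#' @export
impute_mode <- function(column) {
  miss <- is.na(column)
  obs <- column[!miss]
  if (length(obs) == 0L)
    stop_ft("cannot impute an all-missing column", class = "flowtrees_empty_column_error")
  if (!all(obs %in% c(0L, 1L)))
    stop_ft("impute_mode expects a binary column", class = "flowtrees_input_error")
  fill <- if (sum(obs == 1L) > sum(obs == 0L)) 1L else 0L
  out <- as.integer(column)
  out[miss] <- fill
  attr(out, "imputed") <- which(miss)
  out
}

#' Dichotomize the week-36 CD4 count at 450 cells/uL
#'
#' @param cd4_week36 nonnegative counts, none missing (the outcome is never
#'   imputed).
#' @return Object of class `outcome_vector`: integer 0/1 vector with
#'   attribute `"threshold" = 450`.
#' @examples
#' dichotomize_outcome(c(449, 450, 451))  # 0 0 1
#' @export
dichotomize_outcome <- function(cd4_week36) {
  if (anyNA(cd4_week36))
    stop_ft("missing week-36 CD4 count; the outcome is never imputed",
            class = "flowtrees_missing_outcome_error")
  if (any(cd4_week36 < 0))
    stop_ft("CD4 counts must be nonnegative", class = "flowtrees_input_error")
  structure(as.integer(cd4_week36 > 450), threshold = 450, class = "outcome_vector")
}

#' Build the binary analysis matrix and outcome
#'
#' Runs the full preprocessing chain on a dataset: subjects missing the
#' week-36 outcome are dropped (with a warning), every predictor is
#' dichotomized at the median of its observed values, and remaining missing
#' predictor cells are imputed with the observed mode.
#'
#' @param dataset a `flow_dataset` (from [simulate_panel()] /
#'   [read_flow_dataset()]) or a data frame that includes `outcome_column`.
#' @param outcome_column name of the week-36 CD4 count column.
#' @return Object of class `analysis_matrix`: list with `X` (n x p integer
#'   0/1 matrix), `y` (an `outcome_vector`), `medians`, `imputation_log`
#'   (data frame of row/column/value), and `dropped_subjects`.
#' @export
build_analysis_matrix <- function(dataset, outcome_column = "CD4_wk36") {
  values <- if (inherits(dataset, "flow_dataset")) dataset$values else as.data.frame(dataset)
  if (!outcome_column %in% colnames(values))
    stop_ft("outcome column '%s' not found", outcome_column,
            class = "flowtrees_missing_outcome_error")
  drop <- which(is.na(values[[outcome_column]]))
  if (length(drop)) {
    warning(sprintf("dropping %d subject(s) with missing week-36 outcome", length(drop)))
    values <- values[-drop, , drop = FALSE]
  }
  y <- dichotomize_outcome(values[[outcome_column]])
  pred <- values[, setdiff(colnames(values), outcome_column), drop = FALSE]
  n <- nrow(pred)
  X <- matrix(NA_integer_, n, ncol(pred), dimnames = list(rownames(pred), colnames(pred)))
  medians <- setNames(numeric(ncol(pred)), colnames(pred))
  log_rows <- list()
  for (j in seq_len(ncol(pred))) {
    b <- dichotomize_at_median(pred[[j]])
    medians[j] <- attr(b, "median")
    b <- impute_mode(b)
    imp <- attr(b, "imputed")
    if (length(imp))
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(row = imp, column = colnames(pred)[j], value = b[imp])
    X[, j] <- b
  }
  structure(list(X = X, y = y, medians = medians,
                 imputation_log = if (length(log_rows)) do.call(rbind, log_rows)
                                  else data.frame(row = integer(), column = character(),
                                                  value = integer()),
                 dropped_subjects = drop),
            class = "analysis_matrix")
}

#' @export
print.analysis_matrix <- function(x, ...) {
  cat(sprintf("analysis_matrix: %d subjects x %d binary predictors\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  responders: %d/%d; imputed cells: %d; dropped subjects: %d\n",
              sum(x$y), length(x$y), nrow(x$imputation_log), length(x$dropped_subjects)))
  invisible(x)
}

#' Write an analysis matrix as CSV plus a JSON sidecar
#'
#' The CSV holds the 0/1 matrix with the outcome as final column; the
#' sidecar records medians and the imputation log.
#'
#' @param am an `analysis_matrix`.
#' @param path CSV path.
#' @export
write_analysis_matrix <- function(am, path) {
  df <- as.data.frame(am$X, check.names = FALSE)
  df$outcome <- as.integer(am$y)
  write.csv(df, path, row.names = FALSE)
  sidecar <- paste0(sub("\\.csv$", "", path), "_meta.json")
  jsonlite::write_json(list(medians = as.list(am$medians),
                            imputation_log = am$imputation_log,
                            dropped_subjects = am$dropped_subjects),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
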