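#' Construct a survival dataset
#'
#' The universal input container of the package: an `n x p` covariate
#' matrix together with a positive observation time and a right-censoring
#' event indicator per subject (`1` = event observed, `0` = censored at
#' that time).
#'
#' @param covariates numeric matrix (or data frame coercible to one),
#'   subjects in rows, features in columns.
#' @param time positive observation times, length `n`.
#' @param event event indicators in `{0, 1}`, length `n`.
#' @param feature_names optional feature labels; defaults to the matrix
#'   column names or `x1..xp`.
#' @return An object of class `survival_dataset` with elements
#'   `covariates`, `feature_names`, `time`, `event`.
#' @examples
#' d <- survival_dataset(matrix(runif(20), 10, 2), time = 1:10,
#'                       event = rep(1, 10))
#' d
#' @export
survival_dataset <- function(covariates, time, event, feature_names = NULL) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  n <- nrow(covariates)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != n || length(event) != n) {
    stopf("covariates (%d rows), time (%d) and event (%d) must align",
          n, length(time), length(event))
  }
  if (anyNA(covariates) || anyNA(time) || anyNA(event)) {
    stopf("survival_dataset does not accept missing values")
  }
  if (any(time <= 0)) stopf("all observation times must be strictly positive")
  if (!all(event %in% c(0, 1))) stopf("event indicators must be 0 or 1")
  if (is.null(feature_names)) {
    feature_names <- colnames(covariates) %||% paste0("x", seq_len(ncol(covariates)))
  }
  colnames(covariates) <- feature_names
  structure(
    list(covariates = covariates, feature_names = feature_names,
         time = time, event = event),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: %d subjects, %d features, %d events (%.1f%% censored)\n",
              nrow(x$covariates), ncol(x$covariates), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' @export
dim.survival_dataset <- function(x) dim(x$covariates)

#' Subset a survival dataset by row
#'
#' @param dataset a `survival_dataset`.
#' @param idx integer or logical row index.
#' @return The subsetted `survival_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  survival_dataset(dataset$covariates[idx, , drop = FALSE],
                   dataset$time[idx], dataset$event[idx],
                   feature_names = dataset$feature_names)
}

#' Read a survival dataset from CSV
#'
#' Every column other than `time_col` and `event_col` is treated as a
#' feature.  Character/factor columns are label-encoded to the integers
#' `0, 1, ...` in sorted-lexicographic label order, then handled
#' numerically.  Rows containing missing values are dropped with a
#' message giving the count.
#'
#' @param path path to a CSV file with a header row.
#' @param time_col,event_col names of the time and event columns.
#' @return A [survival_dataset()].
#' @seealso [write_survival_csv()] for the inverse operation.
#' @export
read_survival_csv <- function(path, time_col = "time", event_col = "event") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(time_col, event_col), names(df))
  if (length(missing_cols)) {
    stopf("required column(s) missing from %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(df)
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  if (!nrow(df)) stopf("no complete rows in %s", path)
  feat <- df[, setdiff(names(df), c(time_col, event_col)), drop = FALSE]
  feat[] <- lapply(feat, encode_column)
  survival_dataset(as.matrix(feat), time = df[[time_col]],
                   event = df[[event_col]], feature_names = names(feat))
}

# Label-encode a character/factor column by sorted label order; numeric
# columns pass through.
encode_column <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  lv <- sort(unique(as.character(x)))
  as.numeric(match(as.character(x), lv) - 1L)
}

#' Write a survival dataset to CSV
#'
#' Inverse of [read_survival_csv()]: features under their feature names
#' plus `time` and `event` columns, full double precision.
#'
#' @param dataset a `survival_dataset`.
#' @param path output file path.
#' @param time_col,event_col column names to use for time and event.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(dataset, path,
                               time_col = "time", event_col = "event") {
  df <- as.data.frame(dataset$covariates)
  names(df) <- dataset$feature_names
  df[[time_col]] <- dataset$time
  df[[event_col]] <- dataset$event
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rescale every covariate column to the unit interval
#'
#' Min-max rescaling `(x - min) / (max - min)` per column, the
#' preprocessing the networks assume.  Constant columns map to 0.
#'
#' @param dataset a `survival_dataset`.
#' @return The dataset with every covariate column in `[0, 1]`.
#' @export
rescale_unit_interval <- function(dataset) {
  X <- dataset$covariates
  if (!nrow(X)) stopf("cannot rescale an empty dataset")
  X <- apply(X, 2, function(col) {
    r <- range(col)
    if (r[1] == r[2]) rep(0, length(col)) else (col - r[1]) / (r[2] - r[1])
  })
  X <- matrix(X, nrow = nrow(dataset$covariates),
              dimnames = dimnames(dataset$covariates))
  survival_dataset(X, dataset$time, dataset$event, dataset$feature_names)
}

#' Assign subjects to cross-validation folds
#'
#' Randomly partitions `1..n` into `k` folds whose sizes differ by at
#' most one (with `k = 5` each held-out fold is 20% of the data up to a
#' single subject).
#'
#' @param n number of subjects.
#' @param k number of folds (`>= 2`).
#' @param seed integer seed; the same `(n, k, seed)` always yields the
#'   same assignment.
#' @return An object of class `fold_split` with elements `k`,
#'   `assignments` (length-`n` fold index in `1..k`) and `seed`.
#' @export
kfold_split <- function(n, k = 5, seed = 1) {
  if (k < 2) stopf("k must be at least 2")
  if (n < k) stopf("need at least as many subjects (%d) as folds (%d)", n, k)
  assignments <- with_seed(seed, {
    sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
    fold_of <- rep(seq_len(k), times = sizes)
    fold_of[sample.int(n)]
  })
  structure(list(k = k, assignments = assignments, seed = seed),
            class = "fold_split")
}
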