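#' Standardized feature matrix
#'
#' Column-wise z-scoring of the analysis features, retaining the
#' standardization parameters so held-out rows can be transformed with the
#' full-sample moments (the convention used throughout: standardize once on
#' the full sample, never inside resampling loops).
#'
#' @param table A `subject_table` or data frame.
#' @param columns Feature columns (default the eight symptom subscales).
#' @return A `feature_matrix`: list with `values` (n x p z-score matrix,
#'   rownames = subject ids), `features`, `subjects`, `center`, `scale`,
#'   `inverted` (columns whose sign was flipped) and `n_dropped`
#'   (incomplete rows removed).
#' @export
zscore <- function(table, columns = symptom_columns()) {
  missing <- setdiff(columns, names(table))
  if (length(missing) > 0) {
    stop("unknown column(s): ", paste(missing, collapse = ", "))
  }
  cc <- complete_cases_on(as.data.frame(table), columns)
  dat <- cc$data
  if (nrow(dat) < 2) stop("fewer than 2 complete cases")
  x <- as.matrix(dat[, columns, drop = FALSE])
  storage.mode(x) <- "double"
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)  # n - 1 denominator
  degenerate <- columns[scl == 0 | !is.finite(scl)]
  if (length(degenerate) > 0) {
    stop("degenerate feature (constant column): ",
         paste(degenerate, collapse = ", "))
  }
  vals <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  subjects <- if ("subject_id" %in% names(dat)) {
    as.character(dat$subject_id)
  } else {
    as.character(seq_len(nrow(dat)))
  }
  rownames(vals) <- subjects
  structure(list(values = vals, features = columns, subjects = subjects,
                 center = ctr, scale = scl, inverted = character(),
                 n_dropped = cc$n_dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "subjects x",
      ncol(x$values), "features\n")
  cat("features:", paste(x$features, collapse = ", "), "\n")
  if (length(x$inverted)) {
    cat("sign-inverted:", paste(x$inverted, collapse = ", "), "\n")
  }
  if (x$n_dropped > 0) cat("incomplete rows dropped:", x$n_dropped, "\n")
  invisible(x)
}

#' Flip the sign of error-count-like features
#'
#' Measures where larger raw values mean worse performance (e.g. spatial
#' working-memory and set-shifting error counts) are multiplied by -1 so
#' that, across the matrix, higher always means better. Involutive:
#' applying it twice restores the original matrix.
#'
#' @param fm A [zscore()] feature matrix.
#' @param columns Columns to negate.
#' @return The feature matrix with the listed columns negated and recorded
#'   in `$inverted`.
#' @export
invert_sign <- function(fm, columns) {
  stopifnot(inherits(fm, "feature_matrix"))
  unknown <- setdiff(columns, fm$features)
  if (length(unknown) > 0) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  }
  fm$values[, columns] <- -fm$values[, columns]
  fm$inverted <- union(setdiff(fm$inverted, columns),
                       setdiff(columns, fm$inverted))
  fm
}

#' Apply stored standardization parameters to new rows
#'
#' @param fm A `feature_matrix` carrying `center`/`scale`.
#' @param newdata Data frame or matrix with the same feature columns.
#' @return A z-score matrix on the full-sample scale.
#' @export
apply_zscore <- function(fm, newdata) {
  x <- as.matrix(as.data.frame(newdata)[, fm$features, drop = FALSE])
  storage.mode(x) <- "double"
  out <- sweep(sweep(x, 2, fm$center), 2, fm$scale, "/")
  if (length(fm$inverted)) out[, fm$inverted] <- -out[, fm$inverted]
  out
}
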