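#' Pairwise Pearson correlation matrix with significance
#'
#' Pairwise-complete Pearson correlations among the requested columns, with
#' two-sided p values from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom and the per-pair complete-case counts. A Bonferroni
#' column-count-adjusted p matrix is included for transparency (the raw p
#' values are the primary report).
#'
#' @param table Subject table or data frame.
#' @param columns Numeric columns to correlate.
#' @param subset Optional logical vector selecting rows (e.g. membership in
#'   particular clusters).
#' @return A `correlation_matrix`: `r`, `n`, `p`, `p_bonferroni` matrices
#'   and `variables`.
#' @export
pearson_matrix <- function(table, columns, subset = NULL) {
  dat <- as.data.frame(table)
  if (!is.null(subset)) dat <- dat[subset, , drop = FALSE]
  missing <- setdiff(columns, names(dat))
  if (length(missing) > 0) {
    stop("unknown column(s): ", paste(missing, collapse = ", "))
  }
  x <- as.matrix(dat[, columns, drop = FALSE])
  storage.mode(x) <- "double"
  p_len <- length(columns)
  r <- matrix(NA_real_, p_len, p_len, dimnames = list(columns, columns))
  nmat <- matrix(0L, p_len, p_len, dimnames = dimnames(r))
  pmat <- matrix(NA_real_, p_len, p_len, dimnames = dimnames(r))
  for (i in seq_len(p_len)) {
    for (j in i:p_len) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (i == j) {
        r[i, j] <- 1
        next
      }
      if (n < 3) next
      if (stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0) {
        warning("constant column in pair (", columns[i], ", ", columns[j],
                "): correlation undefined")
        next
      }
      rij <- stats::cor(x[ok, i], x[ok, j])
      r[i, j] <- r[j, i] <- rij
      tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(-abs(tt), n - 2)
    }
  }
  n_tests <- p_len * (p_len - 1) / 2
  structure(list(variables = columns, r = r, n = nmat, p = pmat,
                 p_bonferroni = pmin(pmat * n_tests, 1)),
            class = "correlation_matrix")
}

#' Export a correlation heatmap
#'
#' Diverging blue-to-red heatmap of the correlation matrix with each cell
#' annotated to two decimals; undefined cells render neutral with a
#' warning.
#'
#' @param cm A [pearson_matrix()] result.
#' @param path Output image path (PNG/SVG by extension); `NULL` returns the
#'   plot object without writing.
#' @return The ggplot object, invisibly if written.
#' @export
heatmap_export <- function(cm, path = NULL) {
  r <- cm$r
  if (any(is.na(r))) warning("NA correlation cells rendered neutral")
  df <- expand.grid(x = cm$variables, y = cm$variables,
                    stringsAsFactors = FALSE)
  df$r <- as.vector(r)
  df$label <- ifelse(is.na(df$r), "", sprintf("%.2f", df$r))
  df$x <- factor(df$x, levels = cm$variables)
  df$y <- factor(df$y, levels = rev(cm$variables))
  plt <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = label), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1),
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (is.null(path)) return(plt)
  ggplot2::ggsave(path, plt, width = 7, height = 6, dpi = 150)
  invisible(plt)
}
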