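#' Per-group summary statistics
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @return Data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
group_summarize <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  out <- do.call(rbind, lapply(split(values, groups), function(v) {
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}

anova_result <- function(ss_b, ss_w, df_b, df_e, note = NULL) {
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_e
  f <- ms_b / ms_w
  structure(list(F = f, df_between = df_b, df_error = df_e,
                 p = stats::pf(f, df_b, df_e, lower.tail = FALSE),
                 partial_eta_sq = ss_b / (ss_b + ss_w),
                 ss_between = ss_b, ss_error = ss_w,
                 ms_between = ms_b, ms_error = ms_w, note = note),
            class = "anova_result")
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition with the F test and partial eta
#' squared (`SS_effect / (SS_effect + SS_error)`). Complete cases only.
#'
#' @param values Numeric outcome.
#' @param groups Group factor (k >= 2 groups, each with n >= 2).
#' @return An `anova_result` with `F`, `df_between`, `df_error`, `p`,
#'   `partial_eta_sq` and the SS/MS components.
#' @export
anova_oneway <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2) stop("parameter error: need at least 2 groups")
  if (any(sizes < 2)) {
    stop("parameter error: every group needs n >= 2 (smallest has ",
         min(sizes), ")")
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  anova_result(ss_b = tab["groups", "Sum Sq"],
               ss_w = tab["Residuals", "Sum Sq"],
               df_b = tab["groups", "Df"], df_e = tab["Residuals", "Df"])
}

#' One-way ANOVA from published summary statistics
#'
#' Reconstructs the full decomposition from per-group (n, mean, SD) cells —
#' the bridge from printed "mean(SD)" tables to printed F values:
#' `SS_between = sum n_g (m_g - grand)^2`,
#' `SS_within = sum (n_g - 1) SD_g^2`.
#' On raw data this is algebraically identical to [anova_oneway()].
#'
#' @param summary Data frame with columns `n`, `mean`, `sd` (one row per
#'   group), e.g. a [group_summarize()] result or a slice of
#'   [published_group_summaries()].
#' @return An `anova_result`.
#' @export
anova_from_summary <- function(summary) {
  n <- summary$n
  m <- summary$mean
  s <- summary$sd
  stopifnot(length(n) >= 2, all(n >= 2))
  grand <- sum(n * m) / sum(n)
  ss_b <- sum(n * (m - grand)^2)
  ss_w <- sum((n - 1) * s^2)
  anova_result(ss_b, ss_w, df_b = length(n) - 1, df_e = sum(n) - length(n))
}

#' One-way ANCOVA (group effect adjusted for one covariate)
#'
#' General linear model `outcome ~ covariate + group`; the group effect is
#' tested by the extra sum of squares over the covariate-only model, which
#' for a single factor with no interaction coincides with the Type III
#' convention. A constant covariate reduces exactly to the plain ANOVA
#' (noted in the result).
#'
#' @param values Numeric outcome.
#' @param groups Group factor.
#' @param covariate Numeric covariate (e.g. IQ).
#' @return An `anova_result` for the adjusted group effect.
#' @export
ancova_oneway <- function(values, groups, covariate) {
  keep <- !is.na(values) & !is.na(groups) & !is.na(covariate)
  values <- values[keep]
  groups <- factor(groups[keep])
  covariate <- covariate[keep]
  if (stats::sd(covariate) == 0) {
    res <- anova_oneway(values, groups)
    res$note <- "constant covariate: reduces to plain one-way ANOVA"
    return(res)
  }
  full <- stats::lm(values ~ covariate + groups)
  reduced <- stats::lm(values ~ covariate)
  ss_g <- sum(stats::residuals(reduced)^2) - sum(stats::residuals(full)^2)
  ss_e <- sum(stats::residuals(full)^2)
  # covariate absorbing (numerically) all outcome variance: the group
  # extra sum of squares is rounding noise, report a clean zero effect
  ss_tot <- sum((values - mean(values))^2)
  if (ss_g < 1e-12 * ss_tot) ss_g <- 0
  anova_result(ss_g, ss_e, df_b = nlevels(groups) - 1,
               df_e = full$df.residual)
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Pairwise t tests using the pooled within-group mean square on its full
#' error degrees of freedom; adjusted p = min(1, raw p x number of pairs).
#'
#' @param values Numeric outcome.
#' @param groups Group factor.
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `mean_diff`, `t`, `p_raw`, `p_adj`.
#' @export
bonferroni_posthoc <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  an <- anova_oneway(values, groups)
  ms_w <- an$ms_error
  df_e <- an$df_error
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  n_pairs <- ncol(pairs)
  out <- lapply(seq_len(n_pairs), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    va <- values[groups == a]
    vb <- values[groups == b]
    se <- sqrt(ms_w * (1 / length(va) + 1 / length(vb)))
    tt <- (mean(va) - mean(vb)) / se
    p <- 2 * stats::pt(-abs(tt), df_e)
    data.frame(group_a = a, group_b = b, mean_diff = mean(va) - mean(vb),
               t = tt, p_raw = p, p_adj = min(1, p * n_pairs))
  })
  do.call(rbind, out)
}

#' Pearson chi-square test of a contingency table
#'
#' `chi^2 = sum (O - E)^2 / E` with expected counts from the margins, no
#' continuity correction; `df = (rows - 1)(cols - 1)`.
#'
#' @param observed Matrix (or table) of non-negative counts with positive
#'   margins.
#' @return A `contingency_result`: `observed`, `expected`, `chi_square`,
#'   `df`, `p`.
#' @export
chi_square_contingency <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) stop("parameter error: negative count")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0)) {
    stop("parameter error: zero margin in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  structure(list(observed = observed, expected = ct$expected,
                 chi_square = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "contingency_result")
}

#' Per-variable ANOVA table across clusters or groups
#'
#' Applies [anova_oneway()] (or [ancova_oneway()] when a covariate is
#' given) to each variable and collects one row per variable, the layout of
#' the published group- and cluster-comparison tables.
#'
#' @param table Subject table.
#' @param variables Outcome columns.
#' @param groups Grouping vector (e.g. cluster labels or diagnosis).
#' @param covariate Optional covariate vector (e.g. IQ).
#' @return Data frame with columns `variable`, `F`, `df_between`,
#'   `df_error`, `p`, `partial_eta_sq`.
#' @export
anova_table <- function(table, variables, groups, covariate = NULL) {
  rows <- lapply(variables, function(v) {
    res <- if (is.null(covariate)) {
      anova_oneway(table[[v]], groups)
    } else {
      ancova_oneway(table[[v]], groups, covariate)
    }
    data.frame(variable = v, F = res$F, df_between = res$df_between,
               df_error = res$df_error, p = res$p,
               partial_eta_sq = res$partial_eta_sq)
  })
  do.call(rbind, rows)
}
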