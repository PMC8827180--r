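#' Run the full subtyping analysis end to end
#'
#' Executes the stages in order on a cohort table: z-scoring of the symptom
#' features, gap-statistic selection of the cluster count, hierarchical
#' clustering, internal validity indices, subsample stability, discriminant
#' validation (confusion table, resubstitution and cross-validated
#' accuracy, PCA projection), per-variable ANOVA across clusters (with
#' IQ-adjusted ANCOVA for the cognition battery), the cluster-by-diagnosis
#' chi-square, the symptom/cognition/FA correlation grid, and — when the
#' mediation variables are present — the mediation path model with
#' bias-corrected bootstrap intervals. Any stage failure aborts with the
#' stage name.
#'
#' @param config A [run_config()].
#' @param cohort A `subject_table`.
#' @param mediation Optional list with elements `x`, `m`, `y` (column
#'   names) and `clusters` (cluster indices to pool; default 1 and 3).
#'   Defaults to the corpus-callosum / fine-motor / perseveration triple
#'   when those columns exist.
#' @param out_dir Optional directory; when given, stage tables are written
#'   via [write_results()].
#' @return A `pipeline_report` list with all stage outputs.
#' @export
run_pipeline <- function(config, cohort,
                         mediation = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  fm <- stage("preprocess", zscore(cohort, config$feature_columns))
  gap <- stage("gap_statistic",
               gap_statistic(fm, k_max = min(config$k_max,
                                             nrow(fm$values) - 1),
                             B = config$n_reference,
                             seed = child_seed(config$seed, "gap"),
                             linkage = config$linkage))
  k <- max(gap$selected_k, 2)  # downstream validation needs >= 2 clusters
  solution <- stage("cluster",
                    hierarchical_cluster(fm, k = k,
                                         linkage = config$linkage))
  indices <- stage("internal_indices", internal_indices(fm,
                                                        solution$labels))
  stability <- stage("stability",
                     subsample_stability(fm, solution,
                                         n_reps = config$n_stability_reps,
                                         fraction =
                                           config$subsample_fraction,
                                         seed = child_seed(config$seed,
                                                           "stability")))
  lda <- stage("discriminant", fit_lda(fm, solution$labels))
  confusion <- stage("discriminant",
                     confusion_and_accuracy(solution$labels,
                                            predict_lda(lda, fm)))
  cv_acc <- stage("discriminant",
                  cv_lda_accuracy(fm, solution$labels,
                                  seed = child_seed(config$seed, "cv")))
  pca <- stage("discriminant", pca_project(fm, n_components = 3))

  dat <- as.data.frame(cohort)[match(fm$subjects, cohort$subject_id), ]
  labels <- solution$labels
  symptom_anova <- stage("group_stats",
                         anova_table(dat, intersect(config$feature_columns,
                                                    names(dat)), labels))
  cog_cols <- intersect(setdiff(cognition_columns(), "iq"), names(dat))
  cognition_anova <- if (length(cog_cols) > 0 && "iq" %in% names(dat)) {
    stage("group_stats", anova_table(dat, cog_cols, labels,
                                     covariate = dat$iq))
  } else {
    NULL
  }
  contingency <- stage("group_stats", chi_square_contingency(
    table(cluster = labels, diagnosis = dat$diagnosis)))
  corr_cols <- intersect(c(config$feature_columns, cognition_columns(),
                           fa_columns()), names(dat))
  correlations <- stage("association", pearson_matrix(dat, corr_cols))

  if (is.null(mediation) &&
      all(c("fa_cc_body", "ppt_hands", "perseveration") %in% names(dat))) {
    mediation <- list(x = "fa_cc_body", m = "ppt_hands",
                      y = "perseveration", clusters = c(1, 3))
  }
  mediation_fit <- NULL
  mediation_ci <- NULL
  if (!is.null(mediation)) {
    subset <- labels %in% (mediation$clusters %||% c(1, 3))
    sub <- dat[subset, , drop = FALSE]
    mediation_fit <- stage("mediation",
                           fit_path_model(sub, mediation$x, mediation$m,
                                          mediation$y))
    mediation_ci <- stage("mediation",
                          bootstrap_ci(sub, mediation$x, mediation$m,
                                       mediation$y,
                                       n_boot = config$n_bootstrap,
                                       seed = child_seed(config$seed,
                                                         "boot")))
  }

  report <- structure(list(config = config, n_subjects = nrow(fm$values),
                           gap = gap, solution = solution,
                           internal_indices = indices,
                           stability = stability, lda = lda,
                           confusion = confusion, cv_accuracy = cv_acc,
                           pca = pca, symptom_anova = symptom_anova,
                           cognition_anova = cognition_anova,
                           contingency = contingency,
                           correlations = correlations,
                           mediation_fit = mediation_fit,
                           mediation_ci = mediation_ci),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    bundle <- list(
      labels = data.frame(subject_id = fm$subjects, cluster = labels),
      gap_curve = gap$table,
      internal_indices = as.data.frame(indices),
      stability_scores = data.frame(replicate =
                                      seq_along(stability$scores),
                                    ari = stability$scores),
      confusion = as.data.frame(confusion$counts),
      symptom_anova = symptom_anova,
      correlation_r = as.data.frame(correlations$r))
    if (!is.null(cognition_anova)) bundle$cognition_anova <- cognition_anova
    if (!is.null(mediation_ci)) bundle$mediation_ci <- mediation_ci
    report$manifest <- write_results(bundle, out_dir, config = config)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Transdiagnostic subtyping report\n")
  cat("  subjects:", x$n_subjects, "\n")
  cat("  selected k (gap):", x$gap$selected_k,
      "| clustered at k =", x$solution$k, "\n")
  cat(sprintf("  internal indices: silhouette %.3f, CH %.2f, Dunn %.3f\n",
              x$internal_indices$silhouette,
              x$internal_indices$calinski_harabasz,
              x$internal_indices$dunn))
  cat(sprintf("  stability ARI: mean %.3f (min %.3f, max %.3f) over %d reps\n",
              x$stability$mean, x$stability$min, x$stability$max,
              x$stability$n_reps))
  cat(sprintf("  LDA accuracy: resubstitution %.1f%%, %d-fold CV %.1f%%\n",
              100 * x$confusion$accuracy, 5, 100 * x$cv_accuracy))
  cat(sprintf("  cluster x diagnosis chi-square: %.2f (df %d, p %.3g)\n",
              x$contingency$chi_square, x$contingency$df, x$contingency$p))
  if (!is.null(x$mediation_fit)) {
    f <- x$mediation_fit
    cat(sprintf("  mediation: a %.3f, b %.3f, c' %.3f, total %.3f (n %d)\n",
                f$a[1], f$b[1], f$c_prime, f$total_effect, f$n))
  }
  invisible(x)
}
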