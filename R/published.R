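#' Published summary statistics of the reference cohort
#'
#' Transcribed group-level (diagnosis: ASD n=65, ADHD n=47, TDC n=52) and
#' cluster-level (C1 n=67, C2 n=55, C3 n=42) means and standard deviations
#' of the symptom, IQ and cognition variables, the published
#' cluster-prediction confusion counts, and the published mediation-model
#' fit statistics. These are the printed inputs that the summary-statistics
#' ANOVA bridge and the synthetic-cohort defaults consume; subject-level
#' data were never released.
#'
#' @return `published_group_summaries()` and `published_cluster_summaries()` return data frames
#'   with columns `variable`, `group`/`cluster`, `n`, `mean`, `sd`.
#'   `published_confusion()` returns a 3x3 count matrix.
#'   `published_model_fit()` returns the mediation path-model test statistic,
#'   its degrees of freedom, the analysis sample size (clusters 1 and 3
#'   combined) and the printed pairwise correlations among corpus-callosum
#'   FA (X), fine-motor score (M) and perseveration (Y).
#' @name published
NULL

published_csv <- function(file) {
  path <- system.file("extdata", file, package = "transdx")
  if (path == "") path <- file.path("inst", "extdata", file)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname published
#' @export
published_group_summaries <- function() published_csv("published_group_summaries.csv")

#' @rdname published
#' @export
published_cluster_summaries <- function() published_csv("published_cluster_summaries.csv")

#' @rdname published
#' @export
published_confusion <- function() {
  tab <- published_csv("published_confusion_counts.csv")
  m <- as.matrix(tab[, -1])
  dimnames(m) <- list(original = tab$original, predicted = 1:3)
  m
}

#' @rdname published
#' @export
published_model_fit <- function() {
  list(statistic = 10.803, df = 10, n = 109,
       r_xm = 0.28, r_my = -0.22, r_xy = -0.19)
}
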