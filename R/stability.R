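#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected Rand index from the contingency table:
#' `(Index - Expected) / (Max - Expected)`. Invariant to label permutation;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param labels_a,labels_b Label vectors of equal length (>= 2).
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("parameter error: label vectors differ in length")
  }
  n <- length(labels_a)
  if (n < 2) stop("parameter error: need at least 2 observations")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions all-singletons/all-one
  (sum_ij - expected) / (max_index - expected)
}

# nearest-centroid assignment used as the fallback classifier when a
# subsample cluster is too small for a pooled-covariance discriminant fit
nearest_centroid_assign <- function(train_x, train_labels, test_x) {
  labs <- sort(unique(train_labels))
  p <- ncol(train_x)
  centroids <- vapply(labs, function(l) {
    colMeans(train_x[train_labels == l, , drop = FALSE])
  }, numeric(p))
  centroids <- if (p == 1) matrix(centroids, ncol = 1) else t(centroids)
  d2 <- outer(rowSums(test_x^2), rep(1, length(labs))) -
    2 * test_x %*% t(centroids) +
    outer(rep(1, nrow(test_x)), rowSums(centroids^2))
  labs[max.col(-d2, ties.method = "first")]
}

#' Subsample stability of a clustering solution
#'
#' The resampling validation of the reference partition: in each replicate,
#' a random subsample (default 80% of subjects, unstratified) is
#' re-clustered at the reference `k`, a linear discriminant classifier
#' trained on the subsample's cluster labels assigns the held-out
#' subjects, and the combined full-sample labelling is scored against the
#' reference partition with the adjusted Rand index. Subsample features
#' reuse the full-sample standardization (rows of `fm`), matching a single
#' up-front z-scoring of the whole cohort.
#'
#' @param fm Feature matrix used for the reference solution.
#' @param reference A [hierarchical_cluster()] solution on all subjects.
#' @param n_reps Number of replicates.
#' @param fraction Subsample fraction in `(0, 1]`.
#' @param seed Integer seed (replicate seeds are derived from it).
#' @param linkage Agglomeration criterion for the subsample reclustering.
#' @return A `stability_report`: list with `scores` (length `n_reps`),
#'   `mean`, `min`, `max`, `n_fallback` (replicates that used the
#'   nearest-centroid fallback).
#' @export
subsample_stability <- function(fm, reference, n_reps = 1000,
                                fraction = 0.8, seed = 1L,
                                linkage = reference$linkage %||% "ward") {
  x <- feature_values(fm)
  n <- nrow(x)
  stopifnot(length(reference$labels) == n, fraction > 0, fraction <= 1)
  k <- reference$k
  m <- floor(fraction * n)
  if (m < k + 2) stop("subsample too small: fraction*n < k + 2")
  set.seed(child_seed(seed, "stability"))
  rep_seeds <- sample.int(2147483646L, n_reps)
  scores <- numeric(n_reps)
  n_fallback <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    idx <- sample.int(n, m)
    sub_x <- x[idx, , drop = FALSE]
    sub_labels <- hierarchical_cluster(sub_x, k = k,
                                       linkage = linkage)$labels
    full <- integer(n)
    full[idx] <- sub_labels
    hold <- setdiff(seq_len(n), idx)
    if (length(hold) > 0) {
      pred <- tryCatch({
        if (min(table(sub_labels)) < 2) stop("cluster with < 2 members")
        model <- fit_lda(sub_x, sub_labels)
        predict_lda(model, x[hold, , drop = FALSE])
      }, error = function(e) {
        n_fallback <<- n_fallback + 1L
        nearest_centroid_assign(sub_x, sub_labels, x[hold, , drop = FALSE])
      })
      full[hold] <- pred
    }
    scores[r] <- adjusted_rand(reference$labels, full)
  }
  structure(list(scores = scores, mean = mean(scores), min = min(scores),
                 max = max(scores), n_reps = as.integer(n_reps),
                 fraction = fraction, n_fallback = n_fallback),
            class = "stability_report")
}

#' Histogram of subsample adjusted-Rand scores
#'
#' @param report A [subsample_stability()] report.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_stability_hist <- function(report, bins = 30) {
  df <- data.frame(ari = report$scores)
  ggplot2::ggplot(df, ggplot2::aes(x = ari)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = report$mean, linetype = 2) +
    ggplot2::labs(x = "adjusted Rand index vs reference solution",
                  y = "replicates") +
    ggplot2::theme_minimal()
}
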