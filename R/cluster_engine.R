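hclust_method <- function(linkage) {
  switch(linkage, ward = "ward.D2", complete = "complete",
         average = "average",
         stop("unknown linkage: ", linkage))
}

feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

#' Agglomerative hierarchical clustering
#'
#' Bottom-up merging on Euclidean distances under the chosen criterion
#' (Ward's minimum-variance by default), with labels from cutting the tree
#' at `k` clusters. Deterministic given input order; distance ties are
#' broken toward the smallest pair indices (the behaviour of
#' [stats::hclust()]).
#'
#' @param fm A [zscore()] feature matrix (or plain numeric matrix).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param linkage `"ward"`, `"complete"` or `"average"`.
#' @return A `cluster_solution`: list with `labels` (integer vector in
#'   `1..k`, ordered by first appearance), `k`, `tree` (the `hclust`
#'   object) and `linkage`.
#' @export
hierarchical_cluster <- function(fm, k, linkage = "ward") {
  x <- feature_values(fm)
  n <- nrow(x)
  if (k < 1 || k > n) stop("parameter error: k must be in [1, n], got ", k)
  tree <- stats::hclust(stats::dist(x), method = hclust_method(linkage))
  raw <- stats::cutree(tree, k = k)
  # relabel in order of first appearance so the labelling is reading-order
  # deterministic (partition unchanged)
  labels <- match(raw, unique(raw))
  structure(list(labels = labels, k = as.integer(k), tree = tree,
                 linkage = linkage),
            class = "cluster_solution")
}

# pooled within-cluster dispersion W_k = sum_r D_r / (2 n_r), with D_r the
# sum of within-cluster pairwise squared Euclidean distances; equals the
# within-cluster sum of squared deviations from centroids
within_dispersion <- function(x, labels) {
  w <- 0
  for (lab in unique(labels)) {
    xc <- x[labels == lab, , drop = FALSE]
    w <- w + sum(sweep(xc, 2, colMeans(xc))^2)
  }
  w
}

#' Gap statistic for selecting the number of clusters
#'
#' Compares the log within-cluster dispersion of the clustered data to its
#' expectation under `B` reference data sets drawn uniformly over each
#' observed feature's range, each clustered by the same hierarchical
#' algorithm. `Gap(k) = mean_b log W*_kb - log W_k`,
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`, and the selected k is the
#' smallest k with `Gap(k) >= Gap(k+1) - s_{k+1}` (the one-standard-error
#' rule), falling back to `k_max` if no k qualifies.
#'
#' @param fm Feature matrix.
#' @param k_max Largest k scanned (scan starts at 1).
#' @param B Number of reference draws (>= 10).
#' @param seed Integer seed for the reference draws.
#' @param linkage Agglomeration criterion.
#' @return A `gap_curve`: list with `table` (columns `k`, `W_k`, `log_W`,
#'   `E_log_W`, `gap`, `s_k`), `B` and `selected_k`.
#' @export
gap_statistic <- function(fm, k_max = 15, B = 100, seed = 1L,
                          linkage = "ward") {
  x <- feature_values(fm)
  n <- nrow(x)
  stopifnot(k_max >= 1, B >= 10, k_max <= n)
  rng <- apply(x, 2, range)
  if (all(rng[2, ] - rng[1, ] == 0)) {
    stop("degenerate input: all points identical")
  }
  ks <- seq_len(k_max)
  cuts_for <- function(mat) {
    tree <- stats::hclust(stats::dist(mat), method = hclust_method(linkage))
    stats::cutree(tree, k = ks)
  }
  obs_cuts <- cuts_for(x)
  log_w <- log(vapply(ks, function(k) {
    within_dispersion(x, obs_cuts[, k])
  }, numeric(1)))
  set.seed(child_seed(seed, "gap_reference"))
  ref_log_w <- matrix(NA_real_, nrow = B, ncol = k_max)
  for (b in seq_len(B)) {
    ref <- vapply(seq_len(ncol(x)), function(j) {
      stats::runif(n, rng[1, j], rng[2, j])
    }, numeric(n))
    ref_cuts <- cuts_for(ref)
    ref_log_w[b, ] <- log(vapply(ks, function(k) {
      within_dispersion(ref, ref_cuts[, k])
    }, numeric(1)))
  }
  e_log_w <- colMeans(ref_log_w)
  s_k <- apply(ref_log_w, 2, stats::sd) * sqrt(1 + 1 / B)
  gap <- e_log_w - log_w
  selected <- k_max
  for (k in seq_len(k_max - 1)) {
    if (gap[k] >= gap[k + 1] - s_k[k + 1]) {
      selected <- k
      break
    }
  }
  structure(list(table = data.frame(k = ks, W_k = exp(log_w), log_W = log_w,
                                    E_log_W = e_log_w, gap = gap, s_k = s_k),
                 B = as.integer(B), selected_k = as.integer(selected)),
            class = "gap_curve")
}

#' Plot a gap curve
#'
#' @param gap A [gap_statistic()] result.
#' @return A ggplot object (gap vs k with one-SE bars, selected k circled).
#' @export
plot_gap_curve <- function(gap) {
  tab <- gap$table
  sel <- tab[tab$k == gap$selected_k, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = k, y = gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = gap - s_k,
                                          ymax = gap + s_k)) +
    ggplot2::geom_point(data = sel, colour = "red", shape = 1, size = 5) +
    ggplot2::labs(x = "number of clusters k", y = "Gap(k)") +
    ggplot2::theme_minimal()
}

#' Internal cluster validity indices
#'
#' Mean silhouette width (singleton clusters score 0), the
#' Calinski-Harabasz variance-ratio index
#' `[SS_between/(k-1)] / [SS_within/(n-k)]`, and the Dunn index (minimum
#' between-cluster single-linkage distance over maximum within-cluster
#' diameter), all on Euclidean distances in the feature space.
#'
#' @param fm Feature matrix.
#' @param labels Cluster labels (k >= 2, every cluster non-empty).
#' @return List with `silhouette`, `calinski_harabasz`, `dunn`.
#' @export
internal_indices <- function(fm, labels) {
  x <- feature_values(fm)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  labs <- unique(labels)
  k <- length(labs)
  if (k < 2) stop("parameter error: need at least 2 clusters")
  d <- as.matrix(stats::dist(x))

  sil <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)  # singleton convention
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(labs[labs != labels[i]], function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))

  grand <- colMeans(x)
  ss_b <- 0
  ss_w <- 0
  for (l in labs) {
    xc <- x[labels == l, , drop = FALSE]
    ctr <- colMeans(xc)
    ss_b <- ss_b + nrow(xc) * sum((ctr - grand)^2)
    ss_w <- ss_w + sum(sweep(xc, 2, ctr)^2)
  }
  ch <- (ss_b / (k - 1)) / (ss_w / (n - k))

  min_between <- Inf
  max_diam <- 0
  for (i in seq_len(k)) {
    ii <- which(labels == labs[i])
    if (length(ii) > 1) {
      max_diam <- max(max_diam, max(d[ii, ii]))
    }
    for (j in seq_len(k)) {
      if (j <= i) next
      jj <- which(labels == labs[j])
      min_between <- min(min_between, min(d[ii, jj]))
    }
  }
  dunn <- if (max_diam == 0) Inf else min_between / max_diam

  list(silhouette = mean(sil), calinski_harabasz = ch, dunn = dunn)
}
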