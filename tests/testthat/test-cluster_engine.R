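test_that("ward clustering matches the exhaustive best 2-partition on a toy set", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  sol <- hierarchical_cluster(x, k = 2, linkage = "ward")
  # oracle: enumerate all 2-partitions of 4 points, minimize within-SSE
  best <- NULL
  best_sse <- Inf
  for (mask in 1:(2^4 - 2)) {
    g <- as.integer(intToBits(mask))[1:4]
    if (length(unique(g)) < 2) next
    sse <- sum(sapply(unique(g), function(l) {
      v <- x[g == l, 1]
      sum((v - mean(v))^2)
    }))
    if (sse < best_sse) {
      best_sse <- sse
      best <- g
    }
  }
  expect_equal(adjusted_rand(sol$labels, best), 1)
  expect_equal(sol$labels[1], sol$labels[2])
  expect_false(sol$labels[1] == sol$labels[3])
})

test_that("degenerate cuts behave: k = 1, k = n, k > n", {
  x <- matrix(rnorm(40), 10, 4)
  expect_equal(hierarchical_cluster(x, 1)$labels, rep(1L, 10))
  expect_equal(sort(hierarchical_cluster(x, 10)$labels), 1:10)
  expect_error(hierarchical_cluster(x, 11), "parameter error")
})

test_that("tree cuts are nested and label-stable under row permutation", {
  set.seed(21)
  x <- matrix(rnorm(240), 30, 8)
  sol4 <- hierarchical_cluster(x, 4)
  sol3 <- hierarchical_cluster(x, 3)
  # nesting: each k=4 cluster maps into exactly one k=3 cluster
  expect_true(all(tapply(sol3$labels, sol4$labels,
                         function(v) length(unique(v))) == 1))
  # permutation: same partition up to relabeling
  perm <- sample(30)
  sol_p <- hierarchical_cluster(x[perm, ], 4)
  expect_equal(adjusted_rand(sol_p$labels, sol4$labels[perm]), 1)
})

test_that("within-cluster dispersion is positive and non-increasing in k", {
  set.seed(31)
  x <- matrix(rnorm(400), 50, 8)
  gs <- gap_statistic(x, k_max = 10, B = 10, seed = 1)
  expect_true(all(gs$table$W_k > 0))
  expect_true(all(diff(gs$table$W_k) <= 1e-10))
})

test_that("gap statistic selects k = 1 on a single Gaussian blob", {
  set.seed(7)
  x <- matrix(rnorm(100 * 8), 100, 8)
  gs <- gap_statistic(x, k_max = 8, B = 50, seed = 3)
  expect_equal(gs$selected_k, 1L)
  # the selection inequality holds directly at the reported k
  tab <- gs$table
  k <- gs$selected_k
  expect_true(tab$gap[k] >= tab$gap[k + 1] - tab$s_k[k + 1])
})

test_that("gap curve agrees with the reference implementation on fixed data", {
  skip_if_not_installed("cluster")
  set.seed(13)
  x <- planted_symptoms(4, seed = 13)$x
  gs <- gap_statistic(x, k_max = 6, B = 20, seed = 2)
  fun <- function(xx, k) {
    list(cluster = cutree(hclust(dist(xx), method = "ward.D2"), k = k))
  }
  set.seed(2)
  ref <- cluster::clusGap(x, FUNcluster = fun, K.max = 6, B = 20,
                          d.power = 2, spaceH0 = "original",
                          verbose = FALSE)
  # identical observed dispersion curve; clusGap counts each unordered
  # pair once, i.e. W_ref = W/2, so the curves differ by exactly log(2)
  expect_equal(gs$table$log_W - log(2), unname(ref$Tab[, "logW"]),
               tolerance = 1e-10)
  expect_lt(max(abs(gs$table$E_log_W - log(2) - ref$Tab[, "E.logW"])),
            0.15)
})

test_that("internal indices match hand-computed values on a toy set", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c(1, 1, 2, 2)
  idx <- internal_indices(x, labels)
  expect_equal(idx$dunn, 9)                    # min between 9 / max diam 1
  expect_equal(idx$calinski_harabasz, 200)     # (100/1)/(1/2)
  # outer points: a = 1, b = 10.5; inner points: a = 1, b = 9.5
  sil_hand <- mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5))
  expect_equal(idx$silhouette, sil_hand, tolerance = 1e-12)
  expect_error(internal_indices(x, rep(1, 4)), "parameter error")
})

test_that("silhouette agrees with the reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(17)
  x <- matrix(rnorm(200), 25, 8)
  labels <- kmeans(x, 3, nstart = 5)$cluster
  ours <- internal_indices(x, labels)$silhouette
  ref <- mean(cluster::silhouette(labels, dist(x))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-10)
})
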