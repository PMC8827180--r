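test_that("two equal-variance 1-D classes split at the midpoint of means", {
  # exact moments: class means 0 and 2, shared unit variance, equal priors
  x <- matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1)
  y <- rep(1:2, each = 3)
  model <- fit_lda(x, y)
  expect_equal(predict_lda(model, matrix(c(0.99, 1.01, 0.5), ncol = 1)),
               c(1, 2, 1))
  # exact tie goes to the lower class index
  expect_equal(predict_lda(model, matrix(1, ncol = 1)), 1)
  expect_error(predict_lda(model, matrix(1, ncol = 2)), "dimension")
})

test_that("identical class means give zero discriminant eigenvalues", {
  set.seed(4)
  x <- matrix(rnorm(300), 100, 3)
  y <- rep(1:2, 50)
  x <- x - rowsum(x, y)[y, ] / 50  # force equal (zero) class means
  model <- fit_lda(x, y)
  expect_lt(max(abs(model$eigenvalues)), 1e-10)
})

test_that("prediction equals brute-force per-point score evaluation", {
  set.seed(5)
  x <- matrix(rnorm(50 * 4), 50, 4)
  y <- sample(1:3, 50, replace = TRUE)
  model <- fit_lda(x, y)
  pred <- predict_lda(model, x)
  wi <- solve(model$cov)
  brute <- apply(x, 1, function(row) {
    scores <- sapply(seq_along(model$classes), function(g) {
      mu <- model$means[g, ]
      sum(row * (wi %*% mu)) - 0.5 * sum(mu * (wi %*% mu)) +
        log(model$priors[g])
    })
    model$classes[which.max(scores)]
  })
  expect_identical(pred, brute)
})

test_that("predictions agree with the reference LDA implementation", {
  skip_if_not_installed("MASS")
  ps <- planted_symptoms(4, seed = 15)
  model <- fit_lda(ps$x, ps$truth)
  ref <- MASS::lda(ps$x, grouping = ps$truth)
  agree <- mean(predict_lda(model, ps$x) ==
                  as.integer(predict(ref, ps$x)$class))
  expect_gte(agree, 0.99)
})

test_that("accuracy is invariant to per-feature affine rescaling", {
  ps <- planted_symptoms(2, seed = 16)
  labels <- hierarchical_cluster(ps$x, 3)$labels
  acc1 <- confusion_and_accuracy(
    labels, predict_lda(fit_lda(ps$x, labels), ps$x))$accuracy
  scl <- seq(0.1, 5, length.out = ncol(ps$x))
  shifted <- sweep(sweep(ps$x, 2, scl, "*"), 2, 100, "+")
  acc2 <- confusion_and_accuracy(
    labels, predict_lda(fit_lda(shifted, labels), shifted))$accuracy
  expect_equal(acc1, acc2, tolerance = 1e-8)
})

test_that("well-separated planted clusters are classified almost perfectly", {
  ps <- planted_symptoms(4, seed = 17)
  model <- fit_lda(ps$x, ps$truth)
  conf <- confusion_and_accuracy(ps$truth, predict_lda(model, ps$x))
  expect_gte(conf$accuracy, 0.95)
  cv <- cv_lda_accuracy(ps$x, ps$truth, seed = 1)
  expect_gte(cv, 0.9)
})

test_that("published confusion counts reproduce the printed percentages", {
  counts <- published_confusion()
  labels_true <- rep(1:3, times = rowSums(counts))
  labels_pred <- unlist(lapply(1:3, function(i) rep(1:3, counts[i, ])))
  conf <- confusion_and_accuracy(labels_true, labels_pred)
  expect_equal(unname(diag(conf$row_pct)), c(92.5, 94.5, 95.2),
               tolerance = 0.001)
  expect_equal(conf$accuracy, 154 / 164, tolerance = 1e-12)
  expect_equal(unname(rowSums(conf$counts)), c(67, 55, 42))
})

test_that("PCA projection has the declared spectral properties", {
  # perfect collinearity: one component carries everything
  set.seed(6)
  v <- rnorm(40)
  col <- cbind(v, 2 * v)
  pp <- pca_project(col, 2)
  expect_equal(pp$explained[1], 1, tolerance = 1e-10)
  # full reconstruction
  x <- matrix(rnorm(200), 25, 8)
  pp8 <- pca_project(x, 8)
  centered <- scale(x, scale = FALSE)
  expect_equal(pp8$scores %*% t(pp8$loadings), unclass(centered),
               ignore_attr = TRUE, tolerance = 1e-10)
  # sign convention: largest-magnitude loading entry positive
  expect_true(all(apply(pp8$loadings, 2,
                        function(vv) vv[which.max(abs(vv))] > 0)))
  # isotropic data spreads variance roughly evenly
  set.seed(7)
  iso <- matrix(rnorm(5000 * 8), 5000, 8)
  expect_lt(max(abs(pca_project(iso, 8)$explained - 1 / 8)), 0.01)
  expect_error(pca_project(x, 9), "parameter error")
})
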