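#' Fit a linear discriminant model
#'
#' Gaussian classifier with shared within-class covariance: class means,
#' pooled covariance `sum_g sum_{i in g} (x_i - mu_g)(x_i - mu_g)' / (n-k)`
#' stabilized by an unconditional ridge `1e-8 * trace(S)/p * I`, empirical
#' priors `n_g / n`, and discriminant directions from the between/within
#' generalized eigenproblem.
#'
#' @param fm Feature matrix or plain numeric matrix.
#' @param labels Class labels (k >= 2).
#' @param ridge Relative ridge added to the pooled covariance.
#' @return A `discriminant_model`: `classes`, `means` (k x p), `cov`
#'   (pooled, ridged), `priors`, `scaling` (discriminant directions).
#' @export
fit_lda <- function(fm, labels, ridge = 1e-8) {
  x <- feature_values(fm)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(labels) == n)
  classes <- sort(unique(labels))
  k <- length(classes)
  if (k < 2) stop("parameter error: need at least 2 classes")
  sizes <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(sizes < 2)) {
    warning("class with fewer than 2 members; fit is ridge-stabilized")
  }
  means <- vapply(classes, function(cl) {
    colMeans(x[labels == cl, , drop = FALSE])
  }, numeric(p))
  means <- if (p == 1) matrix(means, ncol = 1) else t(means)
  pooled <- matrix(0, p, p)
  for (i in seq_len(k)) {
    xc <- sweep(x[labels == classes[i], , drop = FALSE], 2, means[i, ])
    pooled <- pooled + crossprod(xc)
  }
  pooled <- pooled / (n - k)
  pooled <- pooled + diag(ridge * sum(diag(pooled)) / p, p)
  priors <- sizes / n
  # between-class scatter (prior-weighted), whitened by the pooled covariance
  grand <- colSums(means * priors)
  bc <- sweep(means, 2, grand)
  B <- crossprod(bc * sqrt(priors))
  wi <- solve(pooled)
  eig <- eigen(wi %*% B)
  ord <- order(Re(eig$values), decreasing = TRUE)
  n_dir <- min(k - 1, p)
  scaling <- Re(eig$vectors[, ord[seq_len(n_dir)], drop = FALSE])
  eigenvalues <- Re(eig$values[ord[seq_len(n_dir)]])
  structure(list(classes = classes, means = means, cov = pooled,
                 priors = priors, scaling = scaling,
                 eigenvalues = eigenvalues),
            class = "discriminant_model")
}

#' Predict classes from a linear discriminant model
#'
#' Argmax over classes of the shared-covariance Gaussian discriminant score
#' `x' S^-1 mu_g - mu_g' S^-1 mu_g / 2 + log prior_g`; score ties (within
#' a small numerical tolerance) go to the lowest class index.
#'
#' @param model A [fit_lda()] model.
#' @param fm Feature matrix or numeric matrix with matching columns.
#' @return Predicted class labels.
#' @export
predict_lda <- function(model, fm) {
  x <- feature_values(fm)
  if (ncol(x) != ncol(model$means)) {
    stop("parameter error: feature dimension ", ncol(x),
         " does not match model dimension ", ncol(model$means))
  }
  scores <- lda_scores(model, x)
  # scores within numerical tolerance of the row maximum count as tied;
  # ties resolve to the lowest class index
  top <- apply(scores, 1, max)
  tol <- 1e-9 * (1 + abs(top))
  idx <- apply(scores >= top - tol, 1, which.max)
  model$classes[idx]
}

lda_scores <- function(model, x) {
  wi <- solve(model$cov)
  a <- x %*% wi %*% t(model$means)
  const <- -0.5 * rowSums((model$means %*% wi) * model$means) +
    log(model$priors)
  sweep(a, 2, const, "+")
}

#' Confusion table and classification accuracy
#'
#' @param labels_true,labels_pred Equal-length label vectors (rows =
#'   original clusters, columns = predicted).
#' @return A `confusion_table`: `counts`, `row_pct` (row percentages),
#'   `accuracy` (trace over total).
#' @export
confusion_and_accuracy <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("parameter error: label vectors differ in length")
  }
  levels <- sort(unique(c(labels_true, labels_pred)))
  counts <- table(factor(labels_true, levels = levels),
                  factor(labels_pred, levels = levels))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("original", "predicted")
  row_pct <- 100 * counts / pmax(rowSums(counts), 1)
  accuracy <- sum(diag(counts)) / length(labels_true)
  structure(list(counts = counts, row_pct = row_pct, accuracy = accuracy),
            class = "confusion_table")
}

#' Stratified k-fold cross-validated discriminant accuracy
#'
#' Resubstitution accuracy (the published construction) is optimistic;
#' this reports the complementary stratified cross-validation estimate.
#'
#' @param fm Feature matrix.
#' @param labels Class labels.
#' @param folds Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return Cross-validated accuracy (a single number).
#' @export
cv_lda_accuracy <- function(fm, labels, folds = 5, seed = 1L) {
  x <- feature_values(fm)
  n <- nrow(x)
  set.seed(child_seed(seed, "cv_lda"))
  fold_of <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  correct <- 0
  for (f in seq_len(folds)) {
    test <- fold_of == f
    model <- fit_lda(x[!test, , drop = FALSE], labels[!test])
    pred <- predict_lda(model, x[test, , drop = FALSE])
    correct <- correct + sum(pred == labels[test])
  }
  correct / n
}

#' Principal-component projection
#'
#' Centered data projected on the top eigenvectors of the sample
#' covariance, with each loading vector's sign fixed so its
#' largest-magnitude entry is positive.
#'
#' @param fm Feature matrix.
#' @param n_components Number of components (<= p).
#' @return List with `scores` (n x n_components), `loadings`
#'   (p x n_components) and `explained` (variance fractions).
#' @export
pca_project <- function(fm, n_components = 3) {
  x <- feature_values(fm)
  p <- ncol(x)
  if (n_components > p) {
    stop("parameter error: n_components exceeds feature count")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  list(scores = scores, loadings = load, explained = explained)
}
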