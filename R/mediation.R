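#' Fit a parallel mediation path model by OLS
#'
#' Simple or parallel multiple mediation: `a_j` from the regressions
#' `M_j ~ X`, `b_j` and the direct effect `c'` from
#' `Y ~ X + M_1 + ... + M_k`, indirect effects `a_j b_j`, and the total
#' effect `c = c' + sum a_j b_j` (an exact OLS identity, equal to the
#' coefficient of `Y ~ X`). With `standardize = TRUE` (default) all
#' variables are z-scored first so coefficients are standardized.
#'
#' @param table Data frame holding the variables.
#' @param x Predictor column name.
#' @param mediators Character vector of mediator column names.
#' @param y Outcome column name.
#' @param standardize Z-score all variables before fitting.
#' @return A `mediation_fit`: `a`, `b` (named by mediator), `c_prime`,
#'   `indirect`, `total_indirect`, `total_effect`, `n`.
#' @export
fit_path_model <- function(table, x, mediators, y, standardize = TRUE) {
  vars <- c(x, mediators, y)
  dat <- as.data.frame(table)[, vars, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= length(mediators) + 3) stop("too few complete cases: ", n)
  if (standardize) dat[] <- lapply(dat, function(v) as.numeric(scale(v)))
  preds <- as.matrix(dat[, c(x, mediators), drop = FALSE])
  cm <- stats::cor(preds)
  if (kappa(cm, exact = TRUE) > 1e10) {
    off <- abs(cm)
    diag(off) <- 0
    idx <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("estimation error: collinear predictors (",
         colnames(cm)[idx[1]], ", ", colnames(cm)[idx[2]], ")")
  }
  a <- vapply(mediators, function(m) {
    stats::coef(stats::lm(dat[[m]] ~ dat[[x]]))[2]
  }, numeric(1))
  names(a) <- mediators
  fml <- stats::as.formula(paste(y, "~", paste(c(x, mediators),
                                               collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  b <- cf[mediators]
  c_prime <- unname(cf[x])
  indirect <- a * b
  structure(list(a = a, b = b, c_prime = c_prime, indirect = indirect,
                 total_indirect = sum(indirect),
                 total_effect = c_prime + sum(indirect), n = n),
            class = "mediation_fit")
}

# standardized single-mediator path effects from bootstrap sample moments:
# on z-scored data the OLS coefficients reduce to correlation algebra,
# a = r_XM, b = (r_MY - r_XY r_XM)/(1 - r_XM^2), c' analogous
boot_effects_single <- function(x, m, y, idx) {
  B <- nrow(idx)
  n <- ncol(idx)
  prods <- cbind(x, m, y, x * x, m * m, y * y, x * m, x * y, m * y)
  sums <- matrix(0, B, 9)
  for (j in 1:9) sums[, j] <- rowSums(matrix(prods[idx, j], B, n))
  mn <- sums[, 1:3] / n
  vx <- sums[, 4] / n - mn[, 1]^2
  vm <- sums[, 5] / n - mn[, 2]^2
  vy <- sums[, 6] / n - mn[, 3]^2
  r_xm <- (sums[, 7] / n - mn[, 1] * mn[, 2]) / sqrt(vx * vm)
  r_xy <- (sums[, 8] / n - mn[, 1] * mn[, 3]) / sqrt(vx * vy)
  r_my <- (sums[, 9] / n - mn[, 2] * mn[, 3]) / sqrt(vm * vy)
  den <- 1 - r_xm^2
  a <- r_xm
  b <- (r_my - r_xy * r_xm) / den
  cp <- (r_xy - r_xm * r_my) / den
  cbind(a * b, a * b, cp, cp + a * b)
}

mediation_effects <- function(fit) {
  eff <- c(fit$indirect, total_indirect = fit$total_indirect,
           c_prime = fit$c_prime, total_effect = fit$total_effect)
  names(eff)[seq_along(fit$indirect)] <-
    paste0("indirect_", names(fit$indirect))
  eff
}

#' Bias-corrected bootstrap confidence intervals for mediation effects
#'
#' Case resampling with replacement; for each effect the bias-corrected
#' percentile interval uses `z0 = qnorm(P(boot < estimate))` and bounds at
#' the `pnorm(2 z0 +/- z_(1+level)/2)` percentiles of the bootstrap
#' distribution. (No acceleration constant.)
#'
#' @inheritParams fit_path_model
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Data frame with one row per effect: `effect`, `estimate`,
#'   `lower`, `upper`, `z0`.
#' @export
bootstrap_ci <- function(table, x, mediators, y, n_boot = 10000,
                         level = 0.95, seed = 1L, standardize = TRUE) {
  dat <- as.data.frame(table)[, c(x, mediators, y), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  point <- mediation_effects(
    fit_path_model(dat, x, mediators, y, standardize))
  set.seed(child_seed(seed, "bootstrap_ci"))
  n <- nrow(dat)
  if (length(mediators) == 1 && standardize) {
    # closed-form standardized single-mediator effects, vectorized over
    # resamples (identical to refitting the standardized OLS per resample)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    boots <- boot_effects_single(dat[[x]], dat[[mediators]], dat[[y]], idx)
    colnames(boots) <- names(point)
  } else {
    boots <- matrix(NA_real_, nrow = n_boot, ncol = length(point),
                    dimnames = list(NULL, names(point)))
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boots[bi, ] <- tryCatch(
        mediation_effects(
          fit_path_model(dat[idx, , drop = FALSE], x, mediators, y,
                         standardize)),
        error = function(e) rep(NA_real_, length(point)))
    }
  }
  z_a <- stats::qnorm((1 + level) / 2)
  out <- lapply(names(point), function(nm) {
    bs <- boots[, nm]
    bs <- bs[is.finite(bs)]
    if (length(unique(bs)) == 1) {
      warning("degenerate bootstrap distribution for ", nm,
              ": interval collapses to the point estimate")
      return(data.frame(effect = nm, estimate = point[nm],
                        lower = point[nm], upper = point[nm], z0 = 0))
    }
    prop <- mean(bs < point[nm])
    prop <- min(max(prop, 1 / (length(bs) + 1)),
                length(bs) / (length(bs) + 1))
    z0 <- stats::qnorm(prop)
    qs <- stats::quantile(bs, stats::pnorm(c(2 * z0 - z_a, 2 * z0 + z_a)),
                          names = FALSE, type = 7)
    data.frame(effect = nm, estimate = unname(point[nm]), lower = qs[1],
               upper = qs[2], z0 = z0)
  })
  do.call(rbind, out)
}

# model-implied covariance of a recursive observed-variable path model:
# Sigma = (I - B)^-1 Psi (I - B)^-T, with B the path-coefficient matrix and
# Psi the (block-)diagonal disturbance covariance
implied_sigma <- function(theta, layout) {
  p <- layout$p
  B <- matrix(0, p, p)
  if (layout$q_paths > 0) {
    B[layout$path_idx] <- theta[seq_len(layout$q_paths)]
  }
  psi <- diag(exp(theta[layout$q_paths + seq_len(p)]), p)
  if (layout$q_cov > 0) {
    cov_vals <- theta[layout$q_paths + p + seq_len(layout$q_cov)]
    for (i in seq_len(layout$q_cov)) {
      pair <- layout$cov_pairs[i, ]
      psi[pair[1], pair[2]] <- psi[pair[2], pair[1]] <- cov_vals[i]
    }
  }
  inv <- solve(diag(p) - B)
  inv %*% psi %*% t(inv)
}

#' Maximum-likelihood fit of a recursive path model to a covariance matrix
#'
#' Estimates path coefficients, disturbance variances and (optionally) free
#' covariances among exogenous variables by minimizing the ML discrepancy
#' `F_ML = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - p`. The test
#' statistic is `T = (n - 1) F_ML` at the optimum with
#' `df = p(p+1)/2 - q` free parameters; RMSEA and CFI follow via
#' [fit_indices()] against the independence baseline. Optimization is
#' BFGS from the per-equation OLS solution (exact for recursive models
#' with uncorrelated disturbances) plus jittered restarts.
#'
#' @param sample_cov Positive-definite p x p sample covariance matrix with
#'   dimnames.
#' @param n Sample size behind `sample_cov`.
#' @param paths Data frame with columns `from`, `to` (one row per free
#'   directed path); may have zero rows.
#' @param exog_cov Free the covariances among exogenous variables (default
#'   `TRUE`); with `FALSE` they are fixed to zero, e.g. an independence
#'   model.
#' @param n_restarts Jittered restarts beyond the warm start.
#' @return A `sem_fit`: `coefficients` (the `paths` frame with `estimate`),
#'   `variances`, `statistic` (T), `df`, `F_ML`, `baseline_statistic`,
#'   `baseline_df`, `rmsea`, `cfi`, `n`, `converged`.
#' @export
sem_ml_fit <- function(sample_cov, n, paths = NULL, exog_cov = TRUE,
                       n_restarts = 5) {
  S <- as.matrix(sample_cov)
  p <- nrow(S)
  vars <- rownames(S) %||% paste0("V", seq_len(p))
  dimnames(S) <- list(vars, vars)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("sample covariance is not positive definite")
  }
  if (is.null(paths)) paths <- data.frame(from = character(),
                                          to = character())
  stopifnot(all(c(paths$from, paths$to) %in% vars))
  q_paths <- nrow(paths)
  path_idx <- cbind(match(paths$to, vars), match(paths$from, vars))
  endog <- unique(paths$to)
  exog <- setdiff(vars, endog)
  cov_pairs <- if (exog_cov && length(exog) > 1) {
    t(utils::combn(match(exog, vars), 2))
  } else {
    matrix(integer(), ncol = 2)
  }
  q_cov <- nrow(cov_pairs)
  q <- q_paths + p + q_cov
  df <- p * (p + 1) / 2 - q
  if (df < 0) stop("model not identified: negative degrees of freedom")
  layout <- list(p = p, q_paths = q_paths, path_idx = path_idx,
                 q_cov = q_cov, cov_pairs = cov_pairs)
  log_det_s <- determinant(S, logarithm = TRUE)$modulus

  objective <- function(theta) {
    sigma <- implied_sigma(theta, layout)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) return(1e10)
    as.numeric(determinant(sigma, logarithm = TRUE)$modulus +
                 sum(diag(S %*% solve(sigma))) - log_det_s - p)
  }

  # warm start: equation-wise OLS from S, residual variances, exogenous
  # moments straight from S
  start_coef <- numeric(q_paths)
  start_logvar <- log(diag(S))
  for (v in endog) {
    parents <- paths$from[paths$to == v]
    pi_ <- match(parents, vars)
    vi <- match(v, vars)
    beta <- solve(S[pi_, pi_, drop = FALSE], S[pi_, vi])
    start_coef[paths$to == v] <- beta[match(paths$from[paths$to == v],
                                            parents)]
    start_logvar[vi] <- log(max(S[vi, vi] -
                                  sum(S[vi, pi_] * beta), 1e-8))
  }
  start_cov <- if (q_cov > 0) S[cov_pairs] else numeric(0)
  start <- c(start_coef, start_logvar, start_cov)

  best <- NULL
  set.seed(child_seed(n + q, "sem_restarts"))
  for (r in seq_len(n_restarts + 1)) {
    init <- if (r == 1) start else start + stats::rnorm(length(start), 0, 0.1)
    opt <- tryCatch(
      stats::optim(init, objective, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best) || best$value >= 1e9) {
    stop("estimation error: path-model optimization did not converge")
  }
  f_ml <- max(best$value, 0)
  statistic <- (n - 1) * f_ml
  if (df == 0 && statistic < 1e-6) statistic <- 0
  t0 <- as.numeric((n - 1) * (sum(log(diag(S))) - log_det_s))
  df0 <- p * (p - 1) / 2
  fi <- fit_indices(statistic, df, t0, df0, n)
  theta <- best$par
  coefs <- paths
  if (q_paths > 0) coefs$estimate <- theta[seq_len(q_paths)]
  structure(list(coefficients = coefs,
                 variances = stats::setNames(exp(theta[q_paths +
                                                         seq_len(p)]), vars),
                 statistic = statistic, df = df, F_ML = f_ml,
                 baseline_statistic = t0, baseline_df = df0,
                 rmsea = fi$rmsea, cfi = fi$cfi, n = n,
                 converged = best$convergence == 0),
            class = "sem_fit")
}

#' RMSEA and CFI from ML test statistics
#'
#' `RMSEA = sqrt(max((T - df) / (df (n - 1)), 0))` (0 for a saturated
#' model); `CFI = 1 - max(T - df, 0) / max(T0 - df0, T - df, 0)`, clamped
#' to `[0, 1]`. Conventional cutoffs: RMSEA <= 0.08 reasonable fit,
#' CFI >= 0.90 good fit.
#'
#' @param statistic,df Model test statistic T and degrees of freedom.
#' @param baseline_statistic,baseline_df Independence-baseline T0, df0.
#' @param n Sample size.
#' @return List with `rmsea` and `cfi`.
#' @export
fit_indices <- function(statistic, df, baseline_statistic, baseline_df, n) {
  stopifnot(statistic >= 0, baseline_statistic >= 0, df >= 0,
            baseline_df >= df)
  if (df == 0) {
    if (statistic > 1e-8) {
      stop("invariant violation: df = 0 with positive test statistic")
    }
    rmsea <- 0
  } else {
    rmsea <- sqrt(max((statistic - df) / (df * (n - 1)), 0))
  }
  denom <- max(baseline_statistic - baseline_df, statistic - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(statistic - df, 0) / denom
  list(rmsea = rmsea, cfi = max(0, min(1, cfi)))
}

#' Convenience wrapper: mediation model as a path model
#'
#' Builds the X -> M_j -> Y (plus direct X -> Y) path frame and fits it to
#' the sample covariance of the complete cases with [sem_ml_fit()]. The
#' simple 3-variable model is just-identified (df = 0).
#'
#' @inheritParams fit_path_model
#' @return A `sem_fit`.
#' @export
sem_mediation <- function(table, x, mediators, y, standardize = TRUE) {
  vars <- c(x, mediators, y)
  dat <- as.data.frame(table)[, vars, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (standardize) dat[] <- lapply(dat, function(v) as.numeric(scale(v)))
  paths <- rbind(data.frame(from = x, to = mediators),
                 data.frame(from = c(mediators, x), to = y))
  sem_ml_fit(stats::cov(dat), nrow(dat), paths)
}
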