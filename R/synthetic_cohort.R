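#' Specify a synthetic cohort
#'
#' A cohort specification is a list of strata (diagnostic groups or planted
#' symptom clusters), each with per-column Gaussian means and SDs, plus
#' optional cross-variable correlation blocks generated jointly by a
#' Cholesky transform of a target correlation matrix.
#'
#' @param strata List of strata. Each stratum is a list with elements
#'   `label`, `n` (>= 2), `means` (named numeric), `sds` (named numeric,
#'   >= 0, same names), and either `diagnosis` (a fixed label) or
#'   `diagnosis_probs` (named probabilities over diagnosis labels). An
#'   optional `cluster` element records a planted cluster index.
#' @param blocks List of correlation blocks, each a list with `columns`
#'   (character, length >= 2) and `R` (target correlation matrix: symmetric,
#'   unit diagonal, positive semi-definite).
#' @param fa_cols Columns clipped to `[0, 1]` after generation (clip events
#'   are counted and attached to the result).
#' @param seed Integer seed; the generator derives its stream via
#'   [child_seed()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(strata, blocks = list(), fa_cols = fa_columns(),
                        seed = 1L) {
  for (s in strata) {
    stopifnot(!is.null(s$label), !is.null(s$n), !is.null(s$means),
              !is.null(s$sds))
    if (s$n < 2) stop("spec error: stratum '", s$label, "' has n < 2")
    if (any(s$sds < 0)) stop("spec error: negative SD in stratum '",
                             s$label, "'")
    if (!setequal(names(s$means), names(s$sds))) {
      stop("spec error: means/sds name mismatch in stratum '", s$label, "'")
    }
  }
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    R <- b$R
    nm <- names(blocks)[i] %||% paste0("block", i)
    if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12)) {
      stop("spec error: correlation block '", nm,
           "' is not symmetric with unit diagonal")
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      stop("spec error: correlation block '", nm,
           "' is not positive semi-definite")
    }
    if (length(b$columns) != nrow(R)) {
      stop("spec error: block '", nm, "' column/matrix size mismatch")
    }
  }
  structure(list(strata = strata, blocks = blocks, fa_cols = fa_cols,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# default correlation block: corpus-callosum body FA, fine-motor score and
# perseveration, at the published pairwise correlations
default_blocks <- function() {
  R <- matrix(c(1, 0.28, -0.19,
                0.28, 1, -0.22,
                -0.19, -0.22, 1), 3, 3)
  cols <- c("fa_cc_body", "ppt_hands", "perseveration")
  dimnames(R) <- list(cols, cols)
  list(fa_motor_perseveration = list(columns = cols, R = R))
}

# synthetic calibration of tract-mean FA (no tract means were published):
# plausible pediatric values with the qualitative cluster ordering
# (C1 < C3 in the body of the corpus callosum, C2 < C3 in the splenium,
# C1 < C2 in the internal capsule)
fa_calibration <- function() {
  list(group = list(means = c(fa_cc_body = 0.55, fa_cc_splenium = 0.655,
                              fa_ic = 0.61),
                    sds = c(fa_cc_body = 0.03, fa_cc_splenium = 0.03,
                            fa_ic = 0.025)),
       cluster_means = list(
         `1` = c(fa_cc_body = 0.540, fa_cc_splenium = 0.655, fa_ic = 0.600),
         `2` = c(fa_cc_body = 0.555, fa_cc_splenium = 0.645, fa_ic = 0.615),
         `3` = c(fa_cc_body = 0.565, fa_cc_splenium = 0.665, fa_ic = 0.610)),
       cluster_sds = c(fa_cc_body = 0.03, fa_cc_splenium = 0.03,
                       fa_ic = 0.025))
}

summary_to_named <- function(tab, key) {
  out <- list()
  for (lev in unique(tab[[key]])) {
    sub <- tab[tab[[key]] == lev, ]
    out[[as.character(lev)]] <- list(
      n = sub$n[1],
      means = stats::setNames(sub$mean, sub$variable),
      sds = stats::setNames(sub$sd, sub$variable))
  }
  out
}

#' Default cohort specification by diagnostic group
#'
#' Strata are the three diagnostic groups with the published per-group
#' means and SDs of the symptom subscales, questionnaire totals, IQ and
#' cognition battery; FA tract means use the package's synthetic
#' calibration; the default correlation block ties corpus-callosum FA,
#' fine-motor score and perseveration at the published correlations.
#'
#' @param seed Integer seed.
#' @param blocks Correlation blocks (default [default_blocks]-style).
#' @return A `cohort_spec`.
#' @export
cohort_spec_groups <- function(seed = 1L, blocks = default_blocks()) {
  t1 <- summary_to_named(published_group_summaries(), "group")
  fa <- fa_calibration()$group
  strata <- lapply(c("ASD", "ADHD", "TDC"), function(g) {
    list(label = g, n = t1[[g]]$n, diagnosis = g,
         means = c(t1[[g]]$means, fa$means),
         sds = c(t1[[g]]$sds, fa$sds))
  })
  cohort_spec(strata, blocks = blocks, seed = seed)
}

# pooled (overall) mean and SD per symptom column implied by the published
# group summaries; used to map z-space cluster centroids to raw score units
pooled_symptom_stats <- function() {
  t1 <- published_group_summaries()
  t1 <- t1[t1$variable %in% symptom_columns(), ]
  do.call(rbind, lapply(split(t1, t1$variable), function(sub) {
    N <- sum(sub$n)
    gm <- sum(sub$n * sub$mean) / N
    v <- (sum((sub$n - 1) * sub$sd^2) + sum(sub$n * (sub$mean - gm)^2)) /
      (N - 1)
    data.frame(variable = sub$variable[1], mean = gm, sd = sqrt(v))
  }))
}

# fixed 3-centroid layout in symptom z-space, following the qualitative
# cluster profiles: C1 elevated on the social/communication subscales,
# C3 elevated on inattention/hyperactivity/oppositional symptoms, C2 placed
# so the size-weighted centroid mean is zero
cluster_centroid_layout <- function(n = c(67, 55, 42)) {
  sym <- symptom_columns()
  c1 <- stats::setNames(c(0.9, 0.7, 0.1, 0.1, 0.6, 0.0, -0.1, -0.1), sym)
  c3 <- stats::setNames(c(-0.1, 0.0, 0.1, 0.0, 0.1, 1.0, 0.9, 0.8), sym)
  c2 <- -(n[1] * c1 + n[3] * c3) / n[2]
  list(`1` = c1, `2` = c2, `3` = c3)
}

#' Cohort specification with planted symptom clusters
#'
#' Symptom subscales are generated around three cluster centroids in
#' z-space (then mapped to raw score units via the pooled published
#' moments); IQ and cognition follow the published per-cluster summaries;
#' FA uses the synthetic per-cluster calibration; diagnoses are sampled per
#' cluster so clusters cut across diagnostic labels. The `separation`
#' argument scales the centroid layout so that the *minimum pairwise
#' centroid distance equals `separation` within-cluster SDs* — the single
#' knob for how recoverable the planted structure is.
#'
#' @param n Cluster sizes (default the published 67/55/42).
#' @param separation Minimum pairwise centroid distance in units of the
#'   within-cluster SD. The default 3 is calibrated so the default cohort
#'   reproduces the published solution-quality profile: the gap statistic
#'   detects three overlapping clusters with moderate internal indices and
#'   subsample stability, rather than clean, well-separated blobs.
#' @param z_sd Within-cluster SD in z units. Default 0.8, chosen so the
#'   pooled symptom variance stays near 1 once between-cluster spread is
#'   added.
#' @param seed Integer seed.
#' @param blocks Correlation blocks.
#' @return A `cohort_spec`; generated tables carry a `true_cluster` column.
#' @export
cohort_spec_clusters <- function(n = c(67, 55, 42), separation = 3,
                                 z_sd = 0.8, seed = 1L,
                                 blocks = default_blocks()) {
  stopifnot(length(n) == 3, all(n >= 2), separation > 0, z_sd >= 0)
  layout <- cluster_centroid_layout(n)
  d12 <- sqrt(sum((layout[[1]] - layout[[2]])^2))
  d13 <- sqrt(sum((layout[[1]] - layout[[3]])^2))
  d23 <- sqrt(sum((layout[[2]] - layout[[3]])^2))
  scale <- separation * z_sd / min(d12, d13, d23)
  pooled <- pooled_symptom_stats()
  pmean <- stats::setNames(pooled$mean, pooled$variable)
  psd <- stats::setNames(pooled$sd, pooled$variable)
  t3 <- summary_to_named(published_cluster_summaries(), "cluster")
  fa <- fa_calibration()
  dx_probs <- list(`1` = c(ASD = 0.60, ADHD = 0.15, TDC = 0.25),
                   `2` = c(ASD = 0.25, ADHD = 0.20, TDC = 0.55),
                   `3` = c(ASD = 0.15, ADHD = 0.65, TDC = 0.20))
  sym <- symptom_columns()
  strata <- lapply(1:3, function(ci) {
    key <- as.character(ci)
    centroid <- layout[[key]] * scale
    sym_means <- pmean[sym] + centroid[sym] * psd[sym]
    sym_sds <- stats::setNames(z_sd * psd[sym], sym)
    list(label = paste0("C", ci), n = n[ci], cluster = ci,
         diagnosis_probs = dx_probs[[key]],
         means = c(sym_means, t3[[key]]$means, fa$cluster_means[[key]]),
         sds = c(sym_sds, t3[[key]]$sds, fa$cluster_sds))
  })
  cohort_spec(strata, blocks = blocks, seed = seed)
}

#' Generate a synthetic cohort table
#'
#' Each declared column is drawn Gaussian with its stratum mean and SD;
#' columns belonging to a correlation block are drawn jointly within each
#' stratum by Cholesky transform of the block's target correlation matrix
#' and rescaled to the declared mean/SD. FA columns are clipped to
#' `[0, 1]`; the clip count is attached as attribute `"n_clipped"`.
#'
#' @param spec A [cohort_spec()].
#' @return A `subject_table`. Cluster-structured specs include a
#'   `true_cluster` column.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(child_seed(spec$seed, "cohort"))
  block_cols <- unlist(lapply(spec$blocks, `[[`, "columns"))
  pieces <- lapply(spec$strata, function(s) {
    cols <- names(s$means)
    vals <- matrix(NA_real_, nrow = s$n, ncol = length(cols),
                   dimnames = list(NULL, cols))
    for (b in spec$blocks) {
      bc <- intersect(b$columns, cols)
      if (length(bc) < length(b$columns)) next
      L <- chol(b$R + diag(1e-12, nrow(b$R)))
      z <- matrix(stats::rnorm(s$n * nrow(b$R)), s$n) %*% L
      for (j in seq_along(b$columns)) {
        cn <- b$columns[j]
        vals[, cn] <- s$means[cn] + s$sds[cn] * z[, j]
      }
    }
    for (cn in setdiff(cols, block_cols)) {
      vals[, cn] <- stats::rnorm(s$n, s$means[cn], s$sds[cn])
    }
    dx <- if (!is.null(s[["diagnosis"]])) rep(s[["diagnosis"]], s$n) else
      sample(names(s$diagnosis_probs), s$n, replace = TRUE,
             prob = s$diagnosis_probs)
    out <- data.frame(diagnosis = dx, stringsAsFactors = FALSE)
    if (!is.null(s$cluster)) out$true_cluster <- s$cluster
    cbind(out, as.data.frame(vals))
  })
  tab <- do.call(rbind, pieces)
  tab <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(tab))), tab)
  n_clipped <- 0L
  for (cn in intersect(spec$fa_cols, names(tab))) {
    clip <- tab[[cn]] < 0 | tab[[cn]] > 1
    n_clipped <- n_clipped + sum(clip)
    tab[[cn]] <- pmin(pmax(tab[[cn]], 0), 1)
  }
  extra <- setdiff(names(tab),
                   c("subject_id", "diagnosis", symptom_columns(),
                     cognition_columns(), fa_columns()))
  schema <- subject_schema(
    symptoms = intersect(symptom_columns(), names(tab)),
    cognition = intersect(cognition_columns(), names(tab)),
    fa = intersect(fa_columns(), names(tab)),
    extra = extra)
  out <- as_subject_table(tab, schema)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Generate data from a standardized single-mediator path model
#'
#' Simulates `X` standard normal, `M = a X + e_M`, `Y = c' X + b M + e_Y`,
#' with residual variances chosen so X, M and Y each have unit population
#' variance (the standardized solution). Path tracing gives the population
#' correlations `r_XM = a`, `r_XY = c' + a b`, `r_MY = b + a c'`.
#'
#' @param n Sample size.
#' @param a,b,c_prime Standardized path coefficients.
#' @param seed Integer seed.
#' @return Data frame with columns `X`, `M`, `Y`.
#' @export
generate_mediation_data <- function(n, a, b, c_prime, seed = 1L) {
  v_m <- 1 - a^2
  v_y <- 1 - b^2 - c_prime^2 - 2 * a * b * c_prime
  if (v_m < 0) stop("parameter error: mediator residual variance 1 - a^2 = ",
                    signif(v_m, 4), " is negative")
  if (v_y < 0) stop("parameter error: outcome residual variance ",
                    "1 - b^2 - c'^2 - 2abc' = ", signif(v_y, 4),
                    " is negative")
  set.seed(child_seed(seed, "mediation_data"))
  X <- stats::rnorm(n)
  M <- a * X + stats::rnorm(n, sd = sqrt(v_m))
  Y <- c_prime * X + b * M + stats::rnorm(n, sd = sqrt(v_y))
  data.frame(X = X, M = M, Y = Y)
}
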