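# small in-code fixtures shared across test files

make_tiny_cohort <- function(n = 12, seed = 99) {
  set.seed(seed)
  tab <- data.frame(
    subject_id = sprintf("P%02d", seq_len(n)),
    diagnosis = rep(c("ASD", "ADHD", "TDC"), length.out = n),
    stringsAsFactors = FALSE)
  for (col in symptom_columns()) tab[[col]] <- round(runif(n, 0, 20), 1)
  for (col in cognition_columns()) tab[[col]] <- round(rnorm(n, 100, 10), 1)
  for (col in fa_columns()) tab[[col]] <- round(runif(n, 0.4, 0.7), 3)
  tab
}

# independent pair-counting oracle for the adjusted Rand index
ari_brute <- function(a, b) {
  n <- length(a)
  s_ab <- 0; s_a <- 0; s_b <- 0; npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      s_ab <- s_ab + (sa && sb)
      s_a <- s_a + sa
      s_b <- s_b + sb
      npairs <- npairs + 1
    }
  }
  expected <- s_a * s_b / npairs
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)
  (s_ab - expected) / (max_index - expected)
}

# all set partitions of 1..n as restricted-growth label vectors
set_partitions <- function(n) {
  out <- list()
  rec <- function(labels, i, mx) {
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (l in seq_len(mx + 1)) rec(c(labels, l), i + 1, max(mx, l))
  }
  rec(integer(), 1, 0)
  out
}

# planted 3-cluster symptom matrix in the coordinates it was generated in
planted_symptoms <- function(separation, seed) {
  coh <- generate_cohort(cohort_spec_clusters(separation = separation,
                                              seed = seed))
  list(x = as.matrix(as.data.frame(coh)[, symptom_columns()]),
       truth = coh$true_cluster, cohort = coh)
}

# n x p data whose SAMPLE correlation matrix equals R exactly (empirical
# whitening then recolouring by chol(R))
exact_correlation_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- nrow(R)
  z <- matrix(rnorm(n * p), n, p)
  z <- scale(z, scale = FALSE)
  z <- z %*% solve(chol(cov(z)))
  as.data.frame(z %*% chol(R))
}
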