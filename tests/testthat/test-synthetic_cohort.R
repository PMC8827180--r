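test_that("group-mode cohorts recover the published group means", {
  coh <- generate_cohort(cohort_spec_groups(seed = 1))
  expect_equal(nrow(coh), 164)
  # published AQ totals with 3-SEM bands
  t1 <- published_group_summaries()
  aq <- t1[t1$variable == "aq_total", ]
  for (i in seq_len(nrow(aq))) {
    got <- mean(coh$aq_total[coh$diagnosis == aq$group[i]])
    sem <- aq$sd[i] / sqrt(aq$n[i])
    expect_lt(abs(got - aq$mean[i]), 3 * sem)
  }
  expect_identical(as.integer(table(coh$diagnosis)[c("ASD", "ADHD", "TDC")]),
                   c(65L, 47L, 52L))
})

test_that("degenerate SDs give constant columns and FA stays in range", {
  spec <- cohort_spec(list(list(label = "g", n = 20,
                                means = c(vp = 100, fa_cc_body = 0.99),
                                sds = c(vp = 0, fa_cc_body = 0.2),
                                diagnosis = "TDC")),
                      seed = 3)
  tab <- generate_cohort(spec)
  expect_true(all(tab$vp == 100))
  expect_true(all(tab$fa_cc_body >= 0 & tab$fa_cc_body <= 1))
  expect_gt(attr(tab, "n_clipped"), 0)
})

test_that("correlation blocks hit their targets at large n", {
  R <- matrix(c(1, 0.28, -0.19,
                0.28, 1, -0.22,
                -0.19, -0.22, 1), 3, 3)
  cols <- c("fa_cc_body", "ppt_hands", "perseveration")
  dimnames(R) <- list(cols, cols)
  spec <- cohort_spec(
    list(list(label = "g", n = 10000,
              means = c(fa_cc_body = 0.55, ppt_hands = 34,
                        perseveration = 9),
              sds = c(fa_cc_body = 0.03, ppt_hands = 8,
                      perseveration = 3),
              diagnosis = "TDC")),
    blocks = list(b = list(columns = cols, R = R)), seed = 5)
  tab <- generate_cohort(spec)
  got <- cor(as.data.frame(tab)[, cols])
  expect_lt(max(abs(got - R)), 0.03)
})

test_that("invalid correlation blocks are rejected by name", {
  R_bad <- matrix(c(1, 0.9, -0.9,
                    0.9, 1, 0.9,
                    -0.9, 0.9, 1), 3, 3)
  expect_error(
    cohort_spec(list(list(label = "g", n = 10, means = c(a = 0, b = 0, c = 0),
                          sds = c(a = 1, b = 1, c = 1), diagnosis = "TDC")),
                blocks = list(bad_block = list(columns = c("a", "b", "c"),
                                               R = R_bad))),
    "bad_block")
  expect_error(
    cohort_spec(list(list(label = "g", n = 1, means = c(a = 0),
                          sds = c(a = 1), diagnosis = "TDC"))),
    "n < 2")
})

test_that("mediation generator matches its path-traced population moments", {
  # null model: everything uncorrelated
  null <- generate_mediation_data(1000, 0, 0, 0, seed = 2)
  expect_lt(max(abs(cor(null)[upper.tri(diag(3))])), 0.1)
  # population r_XY = c' + a b by path tracing
  md <- generate_mediation_data(100000, 0.28, -0.181, -0.139, seed = 4)
  expect_lt(abs(cor(md$X, md$Y) - (-0.139 + 0.28 * (-0.181))), 0.01)
  expect_lt(abs(cor(md$X, md$M) - 0.28), 0.01)
  expect_equal(sd(md$Y), 1, tolerance = 0.02)
  # inadmissible standardized solution
  expect_error(generate_mediation_data(10, 0.9, 0.9, 0.9), "negative")
})

test_that("cluster-mode cohorts carry planted structure that scales with separation", {
  coh <- generate_cohort(cohort_spec_clusters(seed = 8))
  expect_equal(as.integer(table(coh$true_cluster)), c(67L, 55L, 42L))
  expect_true(all(c("iq", "ppt_hands", "fa_cc_body") %in% names(coh)))
  # every planted cluster mixes diagnostic labels
  mix <- table(coh$true_cluster, coh$diagnosis)
  expect_true(all(rowSums(mix > 0) >= 2))
  # repeatability
  again <- generate_cohort(cohort_spec_clusters(seed = 8))
  expect_identical(as.data.frame(coh), as.data.frame(again))
})
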