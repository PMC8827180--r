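test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(8)
  v <- rnorm(40)
  g <- rep(c("a", "b"), 20)
  res <- anova_oneway(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("summary-statistics ANOVA is identical to raw-data ANOVA", {
  set.seed(9)
  for (i in 1:5) {
    v <- rnorm(60, sd = runif(1, 0.5, 3))
    g <- sample(c("x", "y", "z"), 60, replace = TRUE)
    raw <- anova_oneway(v, g)
    via_summary <- anova_from_summary(group_summarize(v, g))
    expect_equal(via_summary$F, raw$F, tolerance = 1e-10)
    expect_equal(via_summary$partial_eta_sq, raw$partial_eta_sq,
                 tolerance = 1e-10)
    expect_equal(via_summary$df_error, raw$df_error)
  }
  # equal means: F exactly 0
  s <- data.frame(n = c(10, 12), mean = c(5, 5), sd = c(1, 2))
  expect_equal(anova_from_summary(s)$F, 0)
})

test_that("published group summaries reproduce the printed F values", {
  t1 <- published_group_summaries()
  f_of <- function(var) {
    anova_from_summary(t1[t1$variable == var, ])$F
  }
  printed <- c(iq = 15.206, aq_total = 16.254, snap_total = 31.558,
               socialness = 24.17, mindreading = 7.97,
               perseveration = 6.35, inattention = 23.72,
               hyperactivity = 14.17, odd = 11.22)
  for (v in names(printed)) {
    expect_equal(f_of(v), unname(printed[v]), tolerance = 0.005)
  }
  # near-null rows, absolute comparison at printed precision
  expect_lt(abs(f_of("patterns") - 0.14), 0.01)
  expect_lt(abs(f_of("details") - 1.92), 0.05)
})

test_that("published cluster summaries reproduce the printed effect sizes", {
  t3 <- published_cluster_summaries()
  ppt <- anova_from_summary(t3[t3$variable == "ppt_hands", ])
  expect_equal(ppt$F, 4.51, tolerance = 0.005)
  expect_lt(abs(ppt$partial_eta_sq - 0.053), 0.001)
  expect_equal(ppt$df_between, 2)
  expect_equal(ppt$df_error, 161)
  iq <- anova_from_summary(t3[t3$variable == "iq", ])
  expect_equal(iq$F, 2.15, tolerance = 0.005)
})

test_that("ANCOVA reduces to ANOVA for degenerate covariates and absorbs a perfect one", {
  set.seed(10)
  v <- rnorm(90)
  g <- rep(c("a", "b", "c"), 30)
  const <- ancova_oneway(v, g, rep(1, 90))
  plain <- anova_oneway(v, g)
  expect_equal(const$F, plain$F, tolerance = 1e-10)
  expect_match(const$note, "constant covariate")
  # outcome equal to the covariate: group effect vanishes
  absorbed <- ancova_oneway(v, g, v)
  expect_lt(absorbed$F, 1e-10)
})

test_that("ANCOVA group effect matches the Type III reference", {
  skip_if_not_installed("car")
  set.seed(11)
  g <- factor(rep(c("a", "b", "c"), times = c(20, 25, 30)))
  cov_ <- rnorm(75)
  v <- 0.5 * cov_ + as.numeric(g) * 0.4 + rnorm(75)
  ours <- ancova_oneway(v, g, cov_)
  fit <- lm(v ~ cov_ + g, contrasts = list(g = "contr.sum"))
  ref <- car::Anova(fit, type = "III")
  expect_equal(ours$F, ref["g", "F value"], tolerance = 1e-8)
  expect_equal(ours$p, ref["g", "Pr(>F)"], tolerance = 1e-8)
})

test_that("Bonferroni post-hoc applies the pair-count multiplier", {
  set.seed(12)
  v <- rnorm(90)
  g <- rep(c("a", "b", "c"), 30)
  ph <- bonferroni_posthoc(v, g)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3))
  # two groups: no adjustment
  ph2 <- bonferroni_posthoc(v[g != "c"], g[g != "c"])
  expect_equal(ph2$p_adj, min(1, ph2$p_raw))
  # identical groups (same values relabeled): p caps at 1
  vv <- rep(rnorm(30), 3)
  gg <- rep(c("a", "b", "c"), each = 30)
  expect_true(all(bonferroni_posthoc(vv, gg)$p_adj == 1))
})

test_that("chi-square matches hand and brute-force computation", {
  res <- chi_square_contingency(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(res$chi_square, 20)
  expect_equal(res$df, 1)
  # margin-proportional table: exact independence
  indep <- outer(c(30, 70), c(20, 30, 50)) / 100
  expect_lt(chi_square_contingency(indep)$chi_square, 1e-20)
  # brute-force double loop oracle on a random table
  set.seed(13)
  tab <- matrix(rpois(12, 20) + 1, 3, 4)
  res2 <- chi_square_contingency(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  brute <- 0
  for (i in 1:3) for (j in 1:4) {
    brute <- brute + (tab[i, j] - expected[i, j])^2 / expected[i, j]
  }
  expect_equal(res2$chi_square, brute, tolerance = 1e-12)
  expect_equal(res2$df, 6)
  expect_error(chi_square_contingency(matrix(c(1, 2, 0, 0), 2, 2)),
               "zero margin")
})

test_that("group-size preconditions are enforced", {
  expect_error(anova_oneway(rnorm(5), c("a", "a", "a", "a", "b")),
               "n >= 2")
  expect_error(anova_oneway(rnorm(5), rep("a", 5)), "2 groups")
})
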