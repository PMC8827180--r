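test_that("path coefficients equal the closed-form correlation solution", {
  R <- matrix(c(1, 0.28, -0.19,
                0.28, 1, -0.22,
                -0.19, -0.22, 1), 3, 3)
  dat <- exact_correlation_data(109, R, seed = 3)
  names(dat) <- c("X", "M", "Y")
  fit <- fit_path_model(dat, "X", "M", "Y")
  b_closed <- (-0.22 - (-0.19) * 0.28) / (1 - 0.28^2)
  c_closed <- (-0.19 - 0.28 * (-0.22)) / (1 - 0.28^2)
  expect_equal(unname(fit$a), 0.28, tolerance = 1e-10)
  expect_equal(unname(fit$b), b_closed, tolerance = 1e-10)
  expect_equal(fit$c_prime, c_closed, tolerance = 1e-10)
  expect_equal(fit$total_effect, -0.19, tolerance = 1e-10)
})

test_that("the total-effect identity holds exactly on arbitrary data", {
  set.seed(18)
  for (i in 1:5) {
    n <- 50 + i * 10
    dat <- data.frame(X = rnorm(n), M1 = rnorm(n), M2 = rnorm(n),
                      Y = rnorm(n))
    dat$M1 <- dat$M1 + 0.3 * dat$X
    dat$Y <- dat$Y + 0.2 * dat$X - 0.4 * dat$M1 + 0.1 * dat$M2
    fit <- fit_path_model(dat, "X", c("M1", "M2"), "Y")
    c_total <- coef(lm(scale(Y) ~ scale(X), dat))[2]
    expect_equal(fit$total_effect, unname(c_total), tolerance = 1e-12)
  }
})

test_that("null mediator paths shrink with n and collinearity is caught", {
  md <- generate_mediation_data(100000, 0.4, 0, 0.2, seed = 19)
  fit <- fit_path_model(md, "X", "M", "Y")
  expect_lt(abs(fit$total_indirect), 0.02)
  dup <- md
  dup$X2 <- md$X
  expect_error(fit_path_model(dup, "X", c("X2", "M"), "Y"), "collinear")
})

test_that("bias-corrected bootstrap behaves and reproduces under a seed", {
  md <- generate_mediation_data(200, 0.4, -0.3, 0.1, seed = 20)
  ci1 <- bootstrap_ci(md, "X", "M", "Y", n_boot = 2000, seed = 5)
  ci2 <- bootstrap_ci(md, "X", "M", "Y", n_boot = 2000, seed = 5)
  expect_identical(ci1, ci2)
  ind <- ci1[ci1$effect == "indirect_M", ]
  expect_true(ind$lower <= ind$estimate && ind$estimate <= ind$upper)
  # roughly symmetric bootstrap: z0 near zero, BC close to plain percentile
  expect_lt(abs(ind$z0), 0.15)
  set.seed(child_seed(5, "bootstrap_ci"))
  idx <- matrix(sample.int(200, 200 * 2000, replace = TRUE), 2000, 200)
  boots <- transdx:::boot_effects_single(md$X, md$M, md$Y, idx)[, 1]
  plain <- quantile(boots, c(0.025, 0.975), names = FALSE)
  expect_lt(max(abs(c(ind$lower, ind$upper) - plain)), 0.02)
})

test_that("ML covariance fit reproduces closed-form test statistics", {
  # saturated mediation model: exact fit
  md <- generate_mediation_data(300, 0.3, 0.2, 0.1, seed = 21)
  sat <- sem_mediation(md, "X", "M", "Y")
  expect_equal(sat$statistic, 0)
  expect_equal(sat$df, 0)
  expect_equal(sat$rmsea, 0)
  expect_equal(sat$cfi, 1)
  # two variables, covariance forced to zero: T = -(n-1) log(1 - r^2)
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  ind <- sem_ml_fit(S, n = 101, paths = NULL, exog_cov = FALSE)
  expect_equal(ind$statistic, -100 * log(0.75), tolerance = 1e-4)
  expect_equal(ind$df, 1)
})

test_that("over-identified path models recover parameters and null T level", {
  paths <- data.frame(from = c("X", "M"), to = c("M", "Y"))
  md <- generate_mediation_data(2000, 0.5, 0.4, 0, seed = 22)
  fit <- sem_ml_fit(cov(md), nrow(md), paths)
  est <- fit$coefficients$estimate
  expect_lt(max(abs(est - c(0.5, 0.4))), 0.05)
  expect_equal(fit$df, 1)
  # T is approximately chi-square(df): mean near df over simulations
  ts <- vapply(1:400, function(s) {
    m <- generate_mediation_data(1000, 0.5, 0.4, 0, seed = 1000 + s)
    sem_ml_fit(cov(m), nrow(m), paths, n_restarts = 0)$statistic
  }, numeric(1))
  expect_lt(abs(mean(ts) - 1), 0.15)
})

test_that("fit indices follow their definitions and guard df = 0", {
  fi <- fit_indices(10.803, 10, 500, 15, n = 109)
  expect_lt(abs(fi$rmsea - 0.027), 0.001)
  expect_equal(fit_indices(7, 7, 100, 10, n = 50)$rmsea, 0)
  expect_equal(fit_indices(80, 10, 80, 10, n = 50)$cfi, 0)
  expect_error(fit_indices(3, 0, 100, 10, n = 50), "invariant")
})
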