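test_that("z-scores: worked example, idempotence, degenerate input", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 10, 4)
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z)
  expect_error(standardize(rep(3, 10)), "constant")
  expect_error(standardize(2), "length")
})

test_that("single-predictor standardized beta equals Pearson r", {
  set.seed(5)
  d <- data.frame(x = rnorm(200))
  d$y <- 2 + 0.4 * d$x + rnorm(200)
  fit <- fit_regression(d, "y", "x")
  expect_lt(abs(fit$coefficients$beta_std - cor(d$x, d$y)), 1e-10)
  expect_equal(unname(fit$diagnostics$vif), 1)
})

test_that("regression recovers a known standardized coefficient", {
  set.seed(8)
  n <- 5000
  x <- rnorm(n)
  # beta_std 0.8 with R^2 = 0.64: noise sd 0.6 against unit-variance signal
  y <- 0.8 * x + rnorm(n, sd = 0.6)
  fit <- fit_regression(data.frame(x = x, y = y), "y", "x")
  expect_lt(abs(fit$coefficients$beta_std - 0.8), 0.02)
  expect_true(fit$coefficients$ci_lo < 0.8 && 0.8 < fit$coefficients$ci_hi)
  expect_true(fit$diagnostics$residual_normality_ok)
  expect_true(fit$diagnostics$homoscedasticity_ok)
  expect_gt(fit$diagnostics$durbin_watson, 1.8)
  expect_lt(fit$diagnostics$durbin_watson, 2.2)
})

test_that("regression rejects collinear designs and tiny samples", {
  d <- data.frame(x = rnorm(40))
  d$x2 <- 2 * d$x
  d$y <- d$x + rnorm(40)
  expect_error(fit_regression(d, "y", c("x", "x2")), "singular|collinear")
  expect_error(fit_regression(d[1:8, ], "y", "x"), "at least 10")
})

test_that("Pearson CI: exact correlations and a known interval shape", {
  x <- 1:50
  out <- pearson_with_ci(x, 3 * x + 2)
  expect_equal(out$r, 1)
  expect_equal(out$ci, c(1, 1))
  out2 <- pearson_with_ci(x, -x)
  expect_equal(out2$r, -1)
  set.seed(2)
  a <- rnorm(400); b <- 0.5 * a + rnorm(400, sd = sqrt(0.75))
  out3 <- pearson_with_ci(a, b)
  expect_true(out3$ci[1] < out3$r && out3$r < out3$ci[2])
  # Fisher-z half width shrinks with n
  expect_lt(diff(pearson_with_ci(rnorm(1000), rnorm(1000))$ci), 0.25)
})

test_that("Fisher-z CI coverage is close to nominal under bivariate normal", {
  set.seed(13)
  n <- 400; rho <- 0.5; reps <- 400
  hits <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearson_with_ci(x, y)$ci
    hits <- hits + (ci[1] <= rho && rho <= ci[2])
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.98)
})

test_that("Dunn-Clark test reproduces independently computed statistics", {
  # frozen values computed from the closed-form covariance expressions in
  # an independent numeric environment
  dc <- dunn_clark_test(0.72, 0.46, 0.42, n = 3837)
  expect_equal(dc$z_stat, 20.718520, tolerance = 1e-6)
  expect_lt(dc$p, 0.001)
  small <- dunn_clark_test(0.5, 0.3, 0.2, n = 103)
  expect_equal(small$z_stat, 1.8076454, tolerance = 1e-6)
  expect_equal(small$p, 0.07066171, tolerance = 1e-6)
  orig <- dunn_clark_test(0.5, 0.3, 0.2, n = 103, method = "dunn1969")
  expect_equal(orig$z_stat, 1.8129005, tolerance = 1e-6)
  expect_equal(orig$p, 0.06984717, tolerance = 1e-6)
})

test_that("Dunn-Clark degenerate and invalid cases", {
  eq <- dunn_clark_test(0.5, 0.5, 0.3, n = 100)
  expect_equal(eq$z_stat, 0)
  expect_equal(eq$p, 1)
  expect_error(dunn_clark_test(0.9, -0.9, 0.9, n = 100),
               "positive semi-definite")
  expect_error(dunn_clark_test(0.5, 0.3, 0.2, n = 5), "exceed 10")
})

test_that("Dunn-Clark Z always carries the sign of r1 - r2", {
  set.seed(21)
  for (i in 1:50) {
    # draw a valid correlation matrix via random data
    X <- matrix(rnorm(60), ncol = 3) %*% matrix(rnorm(9), 3)
    R <- cor(X)
    dc <- dunn_clark_test(R[1, 2], R[1, 3], R[2, 3], n = 50)
    expect_equal(sign(dc$z_stat), sign(R[1, 2] - R[1, 3]))
  }
})

test_that("Dunn-Clark type-I error is near nominal under the null", {
  set.seed(17)
  n <- 200; reps <- 600
  L <- chol(matrix(c(1, .4, .4, .4, 1, .3, .4, .3, 1), 3))
  rej <- 0L
  for (i in seq_len(reps)) {
    X <- matrix(rnorm(3 * n), ncol = 3) %*% L
    R <- cor(X)
    p <- dunn_clark_test(R[1, 2], R[1, 3], R[2, 3], n = n)$p
    rej <- rej + (p < 0.05)
  }
  expect_gt(rej / reps, 0.03)
  expect_lt(rej / reps, 0.08)
})

test_that("bootstrap cross-check agrees with Dunn-Clark at cohort scale", {
  set.seed(29)
  n <- 600
  # one variable genuinely more correlated with x than the other
  x <- rnorm(n)
  y1 <- 0.7 * x + rnorm(n, sd = sqrt(1 - 0.49))
  y2 <- 0.3 * x + rnorm(n, sd = sqrt(1 - 0.09))
  dc <- dunn_clark_test(cor(x, y1), cor(x, y2), cor(y1, y2), n = n)
  boots <- replicate(400, {
    idx <- sample.int(n, replace = TRUE)
    cor(x[idx], y1[idx]) - cor(x[idx], y2[idx])
  })
  ci <- quantile(boots, c(0.025, 0.975))
  # both routes must agree that the correlations differ
  expect_lt(dc$p, 0.05)
  expect_true(ci[1] > 0 || ci[2] < 0)
})
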