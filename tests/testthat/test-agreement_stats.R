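test_that("identical paired samples give the degenerate null result", {
  withr::local_seed(41)
  a <- rnorm(30)
  out <- paired_ttest(a, a)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  expect_equal(out$d, 0)
  expect_false(out$degenerate)
})

test_that("zero-mean alternating differences give t = 0 exactly", {
  b <- rnorm(4)
  out <- paired_ttest(b + c(1, -1, 1, -1), b)
  expect_equal(out$t, 0)
  expect_equal(out$dof, 3L)
})

test_that("constant non-zero differences are flagged degenerate", {
  a <- c(1, 2, 3, 4)
  out <- paired_ttest(a + 0.5, a)
  expect_true(out$degenerate)
  expect_true(is.infinite(out$t))
})

test_that("the paired t statistic is antisymmetric under swapping", {
  withr::local_seed(42)
  a <- rnorm(25); b <- rnorm(25, 0.2)
  expect_equal(paired_ttest(a, b)$t, -paired_ttest(b, a)$t)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
})

test_that("paired t-test agrees with stats::t.test on random data", {
  withr::local_seed(43)
  a <- rnorm(40); b <- rnorm(40, 0.1)
  ref <- stats::t.test(a, b, paired = TRUE)
  out <- paired_ttest(a, b)
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$p, ref$p.value)
  expect_equal(out$dof, unname(ref$parameter))
})

test_that("exact linear data recover slope, intercept and R^2 = 1", {
  x <- seq(0, 5, by = 0.5)
  out <- simple_regression(x, 2 * x + 1)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 1)
  expect_equal(out$r_squared, 1)
})

test_that("independent noise gives near-zero R^2 and the F identity holds", {
  withr::local_seed(44)
  x <- rnorm(500); y <- rnorm(500)
  out <- simple_regression(x, y)
  expect_lt(out$r_squared, 0.05)
  n <- out$n
  expect_equal(out$f_stat,
               (n - 2) * out$r_squared / (1 - out$r_squared),
               tolerance = 1e-9)
})

test_that("R^2 equals the squared Pearson correlation", {
  withr::local_seed(45)
  for (i in 1:5) {
    x <- rnorm(50); y <- 0.8 * x + rnorm(50, sd = 0.5)
    expect_equal(simple_regression(x, y)$r_squared,
                 pearson_ci(x, y)$r^2, tolerance = 1e-9)
  }
})

test_that("constant predictors are rejected", {
  expect_error(simple_regression(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_ci(rep(1, 10), rnorm(10)), "constant")
})

test_that("perfectly correlated data give r = +/-1", {
  x <- as.numeric(1:20)
  expect_equal(pearson_ci(x, 3 * x + 2)$r, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)
})

test_that("Fisher confidence interval matches closed-form arithmetic", {
  # r = 0.5, n = 200: z = atanh(0.5), se_z = 1/sqrt(197),
  # CI = tanh(z -/+ 1.96 * se_z) ~ (0.388, 0.599)
  withr::local_seed(46)
  # construct data with sample correlation exactly 0.5 via rotation
  n <- 200
  x <- rnorm(n); e <- stats::residuals(stats::lm(rnorm(n) ~ x))
  xs <- scale(x)[, 1]; es <- scale(e)[, 1]
  r0 <- 0.5
  y <- r0 * xs + sqrt(1 - r0^2) * es
  out <- pearson_ci(xs, y)
  expect_equal(out$r, 0.5, tolerance = 1e-12)
  z <- atanh(0.5); sez <- 1 / sqrt(n - 3)
  expect_equal(out$ci_low, tanh(z - stats::qnorm(0.975) * sez),
               tolerance = 1e-9)
  expect_equal(out$ci_high, tanh(z + stats::qnorm(0.975) * sez),
               tolerance = 1e-9)
  expect_equal(round(c(out$ci_low, out$ci_high), 3), c(0.388, 0.597))
  expect_equal(out$se, sqrt((1 - 0.25) / (n - 2)))
})

test_that("Bland-Altman hand examples and antisymmetry", {
  a <- c(1, 2, 3)
  out <- bland_altman(a, a)
  expect_equal(out$bias, 0)
  expect_equal(out$loa_low, 0)
  expect_equal(out$loa_high, 0)
  b <- c(0, 0); d <- c(-1, 1)
  out2 <- bland_altman(b + d, b)
  expect_equal(out2$bias, 0)
  expect_equal(out2$sd_diff, sqrt(2))
  expect_equal(out2$loa_high, 1.96 * sqrt(2))  # 2.772
  out3 <- bland_altman(a + 0.5, a)
  expect_equal(out3$bias, 0.5)
  expect_equal(out3$loa_low, 0.5)
  expect_equal(out3$loa_high, 0.5)
})

test_that("limits of agreement contain ~95% of Gaussian differences", {
  withr::local_seed(47)
  cover <- vapply(1:20, function(i) {
    b <- rnorm(200)
    a <- b + rnorm(200, 0, 0.3)
    out <- bland_altman(a, b)
    mean(out$table$diff >= out$loa_low & out$table$diff <= out$loa_high)
  }, 0)
  expect_gte(mean(cover), 0.93)   # nominal 95% with sampling tolerance
  expect_true(all(cover >= 0.90))
})

test_that("agreement_report bundles consistent blocks", {
  withr::local_seed(48)
  b <- rnorm(60, 1, 0.2); a <- b + rnorm(60, 0, 0.01)
  rep <- agreement_report(a, b, "step_time")
  expect_equal(rep$n, 60L)
  expect_equal(rep$regression$r_squared, rep$pearson$r^2,
               tolerance = 1e-9)
  expect_true(rep$bland_altman$loa_low <= rep$bland_altman$bias)
  expect_true(rep$bland_altman$bias <= rep$bland_altman$loa_high)
  expect_s3_class(plot_bland_altman(rep), "ggplot")
  expect_s3_class(plot_agreement_regression(a, b, "step_time"), "ggplot")
})
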