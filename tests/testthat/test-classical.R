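test_that("Levene family matches the direct formula and car::leveneTest", {
  # symmetric equal-deviation toy: all z equal, W = 0, p = 1
  r <- levene_family_test(c(0, 2, 0, 2), c(0, 0, 1, 1), center = "mean")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(1, 2, 3, 1, 5, 9)
  r2 <- levene_family_test(y, x, center = "mean")
  expect_equal(r2$statistic, oracle_levene_w(y, x, "mean"), tolerance = 1e-12)

  set.seed(31)
  x3 <- rep(0:2, times = c(20, 15, 10))
  y3 <- rnorm(45, sd = c(1, 2, 3)[x3 + 1])
  for (ctr in c("mean", "median")) {
    ours <- levene_family_test(y3, x3, center = ctr)
    ref <- car::leveneTest(y3, factor(x3), center = if (ctr == "mean") mean else median)
    expect_equal(ours$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }

  expect_error(levene_family_test(y3, rep(0, 45)), "fewer than 2 groups")
  expect_error(levene_family_test(y3[1:21], c(rep(0, 20), 1)), "at least 2")
})

test_that("Bartlett test matches the textbook formula and its degeneracy rules", {
  r <- bartlett_test(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  set.seed(32)
  x <- rep(0:2, times = c(8, 10, 12))
  y <- rnorm(30, sd = c(1, 1.5, 2.5)[x + 1])
  expect_equal(bartlett_test(y, x)$statistic, oracle_bartlett_stat(y, x),
               tolerance = 1e-10)

  expect_error(bartlett_test(y[1:9], c(rep(0, 8), 1)), "at least 2")
  expect_error(bartlett_test(c(1, 1, 1, 2, 5, 9), c(0, 0, 0, 1, 1, 1)),
               "numerical-failure")
})

test_that("CLS handles ties, perfect fits and matches a brute-force rank oracle", {
  r <- cls_test(c(-1, 1, -1, 1), c(0, 0, 1, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  xl <- 1:12
  r2 <- cls_test(3 + 2 * xl, xl)  # exact linear trait
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  set.seed(33)
  x <- runif(12)
  y <- rnorm(12, sd = 1 + x)
  fit <- lm.fit(cbind(1, x), y)
  r3 <- cls_test(y, x)
  expect_equal(r3$statistic, oracle_spearman(fit$residuals^2, x),
               tolerance = 1e-12)
  # t-approximation p-value on n - 2 df
  rho <- r3$statistic
  tt <- rho * sqrt(10 / (1 - rho^2))
  expect_equal(r3$p_value, 2 * pt(-abs(tt), 10), tolerance = 1e-12)

  # exact permutation p-value at small n lies in (0, 1]
  set.seed(34)
  x8 <- rnorm(8)
  y8 <- rnorm(8, sd = exp(x8))
  p8 <- cls_test(y8, x8)$p_value
  expect_true(p8 > 0 && p8 <= 1)
  expect_error(cls_test(y8, rep(1, 8)), "zero variance")
})

test_that("statistics are location-scale invariant in the trait", {
  set.seed(35)
  x <- rep(0:2, times = c(30, 20, 10))
  y <- rnorm(60, mean = x, sd = 1 + 0.3 * x)
  y2 <- 5 * y + 7
  for (m in c("levene", "brown_forsythe", "bartlett", "cls")) {
    a <- run_test(m, y, x)
    b <- run_test(m, y2, x)
    expect_lt(abs(a$statistic - b$statistic), 1e-10)
    expect_lt(abs(a$p_value - b$p_value), 1e-10)
  }
})

test_that("dglm detects a large dispersion effect and rejects degenerate input", {
  set.seed(36)
  x <- rep(c(0, 1), each = 1000)
  y <- rnorm(2000, sd = c(1, 4)[x + 1])
  r <- dglm_test(y, x)
  expect_true(r$converged)
  expect_lt(r$p_value, 1e-6)

  expect_error(dglm_test(y, rep(0, 2000)), "zero variance")
  expect_error(dglm_test(y[1:5], x[1:5]), "at least 6")
})

test_that("dglm converges on nearly all ideal replicates at common allele frequencies", {
  conv <- vapply(1:100, function(i) {
    ds <- make_ideal_dataset(300, 0.2, 0.5, 0.1, seed = seed_stream(37, i))
    dglm_test(ds$y, ds$x)$converged
  }, TRUE)
  expect_gte(mean(conv), 0.95)
})

test_that("the dispatcher enforces covariate compatibility and delegates faithfully", {
  set.seed(38)
  x <- runif(40, 0, 2)
  y <- rnorm(40)
  expect_error(run_test("levene", y, x), "categorical")
  expect_silent(run_test("levene", y, round_dosage(x)))

  ds <- make_ideal_dataset(50, 0.3, 0.5, 0.3, seed = 39)
  expect_identical(run_test("cls", ds$y, ds$x)$p_value,
                   cls_test(ds$y, ds$x)$p_value)
  expect_equal(run_test("brown_forsythe", ds$y, ds$x)$statistic,
               levene_family_test(ds$y, ds$x, center = "median")$statistic,
               tolerance = 1e-12)
  bf <- run_test("bth", ds$y, ds$x)
  expect_null(bf$p_value)
  expect_type(bf$log10_bf, "double")
})

test_that("round_dosage maps dosages to hard calls within {0,1,2}", {
  expect_identical(round_dosage(c(0.2, 0.6, 1.4, 1.8, 2.0)),
                   c(0L, 1L, 1L, 2L, 2L))
})
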