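test_that("discrete genotypes honour degenerate frequencies and binomial moments", {
  expect_true(all(simulate_discrete_genotypes(100, 0, seed = 1) == 0))
  expect_true(all(simulate_discrete_genotypes(100, 1, seed = 1) == 2))
  expect_error(simulate_discrete_genotypes(0, 0.2), "invalid-argument")

  n <- 1e5
  x <- simulate_discrete_genotypes(n, 0.2, seed = 7)
  se <- sqrt(2 * 0.2 * 0.8 / n)
  expect_lt(abs(mean(x) - 0.4), 4 * se)
})

test_that("imputed dosages follow the clipped normal mixture", {
  x0 <- simulate_imputed_genotypes(50, 0, seed = 3)
  expect_true(all(x0 >= 0))                    # |c0| branch only
  x <- simulate_imputed_genotypes(10, 0.5, seed = 3)
  expect_true(all(x >= 0 & x <= 2))

  # Monte-Carlo oracle of the stated mixture (clipped), evaluated directly
  set.seed(11)
  m <- 4e5
  z <- rbinom(m, 2, 0.5)
  sdv <- sqrt(0.5)
  xo <- ifelse(z == 0, abs(rnorm(m, 0, sdv)),
               ifelse(z == 1, rnorm(m, 1, sdv), 2 - abs(rnorm(m, 0, sdv))))
  xo <- pmin(2, pmax(0, xo))
  xs <- simulate_imputed_genotypes(1e5, 0.5, seed = 11)
  se <- sqrt(var(xo) / length(xs) + var(xo) / m)
  expect_lt(abs(mean(xs) - mean(xo)), 4 * se)
})

test_that("ideal trait generator matches its analytic moments", {
  cfg <- sim_config(n = 100, pi_maf = 0.2, beta0 = 1, beta = 2,
                    sigma2 = 1e-12, log_alpha = 0)
  x <- simulate_discrete_genotypes(100, 0.2, seed = 5)
  y <- simulate_trait_ideal(x, cfg, seed = 6)
  expect_lt(max(abs(y - (1 + 2 * x))), 1e-5)

  # variance ratio between genotype groups is alpha^2
  x2 <- rep(c(0, 2), each = 1e5)
  cfg2 <- sim_config(n = length(x2), pi_maf = 0.2, sigma2 = 1,
                     log_alpha = 0.2)
  y2 <- simulate_trait_ideal(x2, cfg2, seed = 8)
  ratio <- var(y2[x2 == 0]) / var(y2[x2 == 2])
  expect_lt(abs(ratio / exp(0.2)^2 - 1), 0.05)

  # zero-mean case
  cfg3 <- sim_config(n = 1e5, pi_maf = 0.2, beta0 = 0, beta = 0, log_alpha = 0)
  x3 <- simulate_discrete_genotypes(1e5, 0.2, seed = 9)
  y3 <- simulate_trait_ideal(x3, cfg3, seed = 10)
  expect_lt(abs(mean(y3)), 4 / sqrt(1e5))

  expect_error(
    simulate_trait_ideal(x, sim_config(n = 100, sigma2 = 1), seed = 1),
    NA)
})

test_that("non-ideal families honour their contracts", {
  x <- simulate_discrete_genotypes(200, 0.3, seed = 2)

  # log-Gaussian trait is exp of the paired ideal draw under a shared seed
  cfg_lg <- sim_config(n = 200, pi_maf = 0.3, beta = 0.5, log_alpha = 0.1,
                       family = "log_gaussian")
  cfg_id <- cfg_lg
  cfg_id$family <- "ideal"
  expect_equal(log(simulate_trait_nonideal(x, cfg_lg, seed = 4)),
               simulate_trait_ideal(x, cfg_id, seed = 4))

  # gamma sign constraint
  expect_error(sim_config(n = 50, beta0 = 1, beta = -1, family = "gamma"),
               "invalid-argument")
  cfg_g <- sim_config(n = 200, beta0 = 1, beta = 0.5, family = "gamma")
  yg <- simulate_trait_nonideal(x, cfg_g, seed = 4)
  expect_true(all(yg >= 0))

  # additive variance positivity
  cfg_a <- sim_config(n = 200, sigma2 = 1, log_alpha = -0.4,
                      family = "additive_variance")
  xa <- c(x[x < 2], 2, 2)
  expect_silent(simulate_trait_nonideal(xa, cfg_a, seed = 4))
  cfg_a$log_alpha <- -0.51
  expect_error(simulate_trait_nonideal(rep(2, 10), cfg_a, seed = 4),
               "invalid-argument")
})

test_that("bimodal mixture hits the analytic mixture-weight fraction", {
  n <- 1e5
  cfg <- sim_config(n = n, beta0 = 0, beta = 0, log_alpha = 0,
                    family = "bimodal", lambda_mix = 0.4)
  x <- simulate_discrete_genotypes(n, 0.2, seed = 13)
  y <- simulate_trait_nonideal(x, cfg, seed = 14)
  frac <- mean(y > 7 & y < 13)
  # N(10,1) mass in (7,13) = pnorm(3) - pnorm(-3); base component contributes
  # essentially nothing at beta0 = 0
  expected <- 0.4 * (pnorm(3) - pnorm(-3))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("benchmark suites pair each replicate with one permutation null, deterministically", {
  cfg <- sim_config(n = 60, pi_maf = 0.3, beta = 0.5, log_alpha = 0.2)
  suite <- generate_benchmark_suite(cfg, reps = 1, seed = 3)
  expect_length(suite, 2)
  expect_equal(vapply(suite, `[[`, TRUE, "is_permutation_null"),
               c(FALSE, TRUE))

  suite50 <- generate_benchmark_suite(cfg, reps = 50, seed = 3)
  expect_length(suite50, 100)
  expect_equal(sum(vapply(suite50, `[[`, TRUE, "is_permutation_null")), 50)

  again <- generate_benchmark_suite(cfg, reps = 50, seed = 3)
  expect_identical(suite50, again)

  # permutation null keeps the same covariate and permutes residuals only
  d <- suite50[[1]]
  p <- suite50[[2]]
  expect_identical(d$x, p$x)
  fit <- lm.fit(cbind(1, d$x), d$y)
  expect_equal(sort(p$y - fit$fitted.values), sort(fit$residuals),
               tolerance = 1e-12)
})

test_that("hypothesis classes partition the (beta, log alpha) grid", {
  grid <- expand.grid(beta = c(0, 0.2, 0.5, 1),
                      log_alpha = c(-0.2, -0.1, 0, 0.1, 0.2))
  cls <- mapply(hypothesis_class, grid$beta, grid$log_alpha)
  expect_setequal(unique(cls), c("strong_null", "weak_null",
                                 "weak_alternative", "strong_alternative"))
  expect_equal(unname(cls[grid$beta == 0 & grid$log_alpha == 0]), "strong_null")
  expect_true(all(cls[grid$beta != 0 & grid$log_alpha == 0] == "weak_null"))
  expect_true(all(cls[grid$beta == 0 & grid$log_alpha != 0] == "weak_alternative"))
  expect_true(all(cls[grid$beta != 0 & grid$log_alpha != 0] == "strong_alternative"))
})

test_that("suite TSV round trip preserves data and manifest", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n = 30, pi_maf = 0.3, beta = 0.2, log_alpha = -0.1)
  suite <- generate_benchmark_suite(cfg, reps = 3, seed = 9)
  write_benchmark_suite(suite, dir)
  back <- read_benchmark_suite(dir)
  expect_length(back, 6)
  for (i in seq_along(suite)) {
    expect_equal(back[[i]]$y, suite[[i]]$y)
    expect_equal(back[[i]]$x, suite[[i]]$x)
    expect_equal(back[[i]]$hypothesis_class, suite[[i]]$hypothesis_class)
    expect_equal(back[[i]]$is_permutation_null, suite[[i]]$is_permutation_null)
  }
})
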