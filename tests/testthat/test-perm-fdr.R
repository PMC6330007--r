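test_that("mean-preserving permutation shuffles residuals without altering them", {
  ds <- make_ideal_dataset(100, 0.3, 0.8, 0.4, seed = 41)
  py <- mean_preserving_permutation(ds$y, ds$x, seed = 42)
  fit <- lm.fit(cbind(1, ds$x), ds$y)
  expect_equal(sort(as.numeric(py) - fit$fitted.values), sort(fit$residuals),
               tolerance = 1e-12)
  expect_equal(mean(py), mean(ds$y), tolerance = 1e-12)
  expect_gte(attr(py, "slope_p"), 0.10)
  expect_error(mean_preserving_permutation(ds$y, rep(0, 100)), "zero variance")
})

test_that("permutation keeps mean effects but removes variance effects", {
  hits <- 0
  slope_ok <- 0
  for (i in 1:200) {
    ds <- make_ideal_dataset(300, 0.3, 0.8, 0.4, seed = seed_stream(43, i))
    py <- as.numeric(mean_preserving_permutation(ds$y, ds$x,
                                                 seed = seed_stream(44, i)))
    fit0 <- summary(lm(ds$y ~ ds$x))$coefficients
    fitp <- summary(lm(py ~ ds$x))$coefficients
    if (abs(fitp["ds$x", 1] - fit0["ds$x", 1]) <= 2 * fit0["ds$x", 2]) {
      slope_ok <- slope_ok + 1
    }
    if (levene_family_test(py, ds$x)$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(slope_ok / 200, 0.95)
  expect_gte(hits / 200, 0.90)
})

test_that("FDR estimates equal the direct exceedance-count ratio", {
  expect_equal(estimate_fdr(c(3, 2, 1), c(1.5, 0.5, 0.2), 1.4), 0.5)
  expect_equal(estimate_fdr(c(3, 2, 1), c(1.5, 0.5, 0.2), 5), 0)
  expect_equal(estimate_fdr(c(3, 2, 1), c(3, 2, 1), 0.5), 1)

  set.seed(45)
  for (rep in 1:20) {
    real <- rnorm(sample(5:100, 1))
    perm <- rnorm(sample(5:100, 1))
    t <- rnorm(1)
    brute <- if (sum(real > t) == 0) 0 else sum(perm > t) / sum(real > t)
    expect_identical(estimate_fdr(real, perm, t), brute)
  }
  # absolute-value comparison for signed Bayes factors
  expect_equal(estimate_fdr(c(-3, 2), c(-2.5, 0.1), 1.9, absolute = TRUE), 0.5)
})

test_that("threshold calibration scans observed scores and lists discoveries", {
  cal <- calibrate_threshold(c(3, 2, 1), c(0.1, 0.1, 0.1), level = 0.05)
  expect_lte(cal$d_fdr, 1)
  expect_equal(cal$n_discoveries, 3)
  expect_equal(cal$discoveries$score, c(3, 2, 1))

  same <- calibrate_threshold(c(3, 2, 1), c(3, 2, 1), level = 0.05)
  expect_equal(same$n_discoveries, 0)

  # permutation scores dominating everywhere: no discoveries at any level
  dom <- calibrate_threshold(c(1, 0.5), c(2, 1.5), level = 0.05)
  expect_equal(dom$n_discoveries, 0)
  expect_error(calibrate_threshold(1:3, 1:3, level = 1.2), "invalid-argument")
})

test_that("FDR curves report ascending thresholds with non-negative estimates", {
  fc <- fdr_curve(rnorm(50, 1), rnorm(50))
  expect_true(!is.unsorted(fc$thresholds))
  expect_true(all(fc$fdr_at >= 0))
  expect_equal(fc$n_real, 50)
})

test_that("MAF-stratified calibration reduces to global with one bin and respects strata", {
  set.seed(46)
  sc <- data.frame(score = c(rnorm(100, 2), rnorm(100)),
                   maf = runif(200, 0.06, 0.49),
                   is_perm = rep(c(FALSE, TRUE), each = 100),
                   id = 1:200)
  one_bin <- maf_stratified_fdr(sc, level = 0.05, bins = c(0.05, 0.5))
  glob <- calibrate_threshold(sc$score[!sc$is_perm], sc$score[sc$is_perm],
                              0.05, ids = sc$id[!sc$is_perm])
  expect_equal(one_bin[[1]]$d_fdr, glob$d_fdr)
  expect_equal(one_bin[[1]]$n_discoveries, glob$n_discoveries)

  # scores concentrated in one bin: discoveries only from the populated bin
  sc2 <- sc
  sc2$maf <- ifelse(sc2$is_perm, 0.07, 0.07)  # everything in [0.05, 0.1)
  two <- suppressWarnings(maf_stratified_fdr(sc2, 0.05,
                                             bins = c(0.05, 0.1, 0.5)))
  expect_true(all(two$discoveries$maf_bin == "[0.05,0.1)"))

  # inflated low-MAF stratum: stratified discoveries in the low bin cannot
  # exceed the global count restricted to that bin
  set.seed(47)
  low_real <- rnorm(80, 3)    # inflated scores at low MAF
  low_perm <- rnorm(80, 2.6)  # ... but inflated in the permutations too
  hi_real <- rnorm(80, 1.5)
  hi_perm <- rnorm(80, 0)
  sc3 <- data.frame(score = c(low_real, hi_real, low_perm, hi_perm),
                    maf = rep(c(0.07, 0.4, 0.07, 0.4), each = 80),
                    is_perm = rep(c(FALSE, TRUE), each = 160),
                    id = 1:320)
  strat <- maf_stratified_fdr(sc3, 0.05, bins = c(0.05, 0.1, 0.5))
  glob3 <- calibrate_threshold(sc3$score[!sc3$is_perm],
                               sc3$score[sc3$is_perm], 0.05,
                               ids = sc3$id[!sc3$is_perm])
  glob_low <- sum(glob3$discoveries$id <= 80)
  strat_low <- sum(strat$discoveries$maf_bin == "[0.05,0.1)")
  expect_lte(strat_low, glob_low)
})
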