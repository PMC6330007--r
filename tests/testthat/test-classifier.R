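test_that("the default reference bank has 79 standardized densities", {
  bank <- reference_bank()
  expect_length(bank, 79)
  expect_false(anyDuplicated(attr(bank, "ids")) > 0)

  # moment matching: standardized samplers have population mean 0, var 1
  set.seed(51)
  for (i in c(1, 5, 20, 30, 45, 60, 79)) {
    z <- bank[[i]]$sampler(2e5)
    expect_lt(abs(mean(z)), 4 * sd(z) / sqrt(2e5))
    expect_lt(abs(var(z) - 1), 0.05)
  }
})

test_that("one-sided KS features match a brute-force ECDF comparison", {
  q <- c(0.1, 0.4, 0.5, 0.9, 1.3)
  r <- c(0.2, 0.3, 0.8, 1.0, 1.1)
  expect_equal(hetvar:::ks_dplus(q, r), oracle_ks_dplus(q, r),
               tolerance = 1e-12)
  set.seed(52)
  for (rep in 1:10) {
    q <- rnorm(sample(5:40, 1))
    r <- rnorm(sample(5:40, 1), 0.3)
    expect_equal(hetvar:::ks_dplus(q, r), oracle_ks_dplus(q, r),
                 tolerance = 1e-12)
  }
})

test_that("feature vectors have bank dimension, are deterministic, and reject degenerate input", {
  bank <- reference_bank()
  set.seed(53)
  y <- rnorm(200, 5, 2)
  f1 <- ks_feature_vector(y, bank, ref_size = 50, seed = 7)
  f2 <- ks_feature_vector(y, bank, ref_size = 50, seed = 7)
  expect_length(f1, 79)
  expect_identical(f1, f2)
  # Gaussian sample vs its own matched Gaussian reference: small statistic
  fbig <- ks_feature_vector(rnorm(1000, 5, 2), bank, ref_size = 1000, seed = 8)
  expect_lt(fbig[["gaussian"]], 0.1)
  expect_error(ks_feature_vector(rep(1, 50), bank), "zero variance")
  expect_error(ks_feature_vector(y[1:10], bank), "at least 20")
})

test_that("training sets have the 7 x 4 x reps design and are reproducible", {
  bank <- reference_bank()
  ts1 <- build_training_set(n = 60, samples_per_cell = 1, bank = bank,
                            ref_size = 30, seed = 5)
  expect_equal(nrow(ts1$features), 28)
  expect_equal(as.vector(table(ts1$labels)), rep(4L, 7))
  ts2 <- build_training_set(n = 60, samples_per_cell = 1, bank = bank,
                            ref_size = 30, seed = 5)
  expect_identical(ts1, ts2)
})

test_that("the classifier beats chance and its probabilities normalize", {
  bank <- reference_bank()
  ts <- build_training_set(n = 150, samples_per_cell = 10, bank = bank,
                           ref_size = 60, seed = 6)
  clf <- train_classifier(ts, folds = 5, ntree = 150, seed = 6)
  expect_gt(clf$macro_accuracy, 1 / 7)

  ds <- make_ideal_dataset(150, 0.2, 0.5, 0.2, seed = 61)
  res <- classify_and_recommend(ds$y, ds$x, classifier = clf, bank = bank,
                                ref_size = 60, seed = 9)
  expect_equal(sum(res$probabilities), 1, tolerance = 1e-9)
  expect_s3_class(res$transform, "transform_spec")

  # shuffled labels destroy the signal
  ts_sh <- ts
  set.seed(62)
  ts_sh$labels <- sample(ts_sh$labels)
  clf_sh <- train_classifier(ts_sh, folds = 5, ntree = 150, seed = 6)
  se <- sqrt((1 / 7) * (6 / 7) / length(ts$labels))
  expect_lt(clf_sh$macro_accuracy, 1 / 7 + 3 * se)
})

test_that("transformations honour their domains and inverses", {
  set.seed(63)
  z <- rnorm(80)
  expect_equal(as.numeric(apply_transformation(exp(z), transform_spec("log"))),
               z, tolerance = 1e-12)
  y <- rgamma(80, 2)
  s <- apply_transformation(y, transform_spec("mean_centered_sqrt"))
  expect_lt(abs(mean(s)), 1e-12)
  expect_equal(attr(s, "spec")$offset, mean(sqrt(y)))
  expect_error(apply_transformation(c(0, 1, 2), transform_spec("log")),
               "invalid-argument")
  expect_error(apply_transformation(c(-1, 1), transform_spec("mean_centered_sqrt")),
               "invalid-argument")

  expect_equal(recommend_transformation("log_gaussian")$kind, "log")
  expect_equal(recommend_transformation("gamma")$kind, "mean_centered_sqrt")
  expect_equal(recommend_transformation("bth_ideal")$kind, "none")
})
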