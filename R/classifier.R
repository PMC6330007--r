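# Trait-distribution classifier: generates labelled KS feature vectors from
# the seven trait families, trains a random forest, and maps predicted
# classes to prescriptive transformations.

CLASS_LABELS <- c("bth_ideal", "additive_variance", "exponential_mean",
                  "exponential_residual", "log_gaussian", "gamma", "bimodal")

# Trait draw for one classifier class.  beta0 conventions: gamma uses
# beta0 = 2 so the gamma mean stays positive over x in [0, 2]; the
# exponential-mean class exponentiates the linear predictor.  The
# exponential-mean and exponential-residual classes are conventions of this
# package: the former puts the heteroskedastic Gaussian noise around an
# exponential mean curve, the latter uses centred exponential residuals
# scaled to the ideal model's variance function.
simulate_class_trait <- function(label, x, beta, log_alpha, sigma2 = 1,
                                 seed = NULL) {
  n <- length(x)
  base_cfg <- function(family, beta0 = 0) {
    sim_config(n = max(n, 4), pi_maf = 0.2, beta0 = beta0, beta = beta,
               sigma2 = sigma2, log_alpha = log_alpha, family = family)
  }
  switch(label,
    bth_ideal = simulate_trait_ideal(x, base_cfg("ideal"), seed),
    additive_variance = {
      # additive coefficient kept safely above -sigma2/2 on x in [0,2]
      a <- 0.4 * sign(log_alpha) * (log_alpha != 0)
      cfg <- base_cfg("additive_variance")
      cfg$log_alpha <- abs(a)  # positive additive effect
      simulate_trait_nonideal(x, cfg, seed)
    },
    log_gaussian = simulate_trait_nonideal(x, base_cfg("log_gaussian"), seed),
    gamma = {
      cfg <- base_cfg("gamma", beta0 = 2)
      cfg$beta <- abs(beta)
      simulate_trait_nonideal(x, cfg, seed)
    },
    bimodal = simulate_trait_nonideal(x, base_cfg("bimodal"), seed),
    exponential_mean = with_seed(seed, {
      mu <- exp(0.5 + beta * x)
      stats::rnorm(n, mu, sqrt(sigma2) * exp(-log_alpha * x / 2))
    }),
    exponential_residual = with_seed(seed, {
      sdv <- sqrt(sigma2) * exp(-log_alpha * x / 2)
      beta * x + (stats::rexp(n) - 1) * sdv
    }),
    stopf("invalid-argument: unknown class label '%s'", label))
}

#' Build a labelled training set of KS feature vectors
#'
#' For each of the seven trait-distribution classes and each of the four
#' (variance effect, mean effect) zero/non-zero configurations,
#' `samples_per_cell` datasets are simulated (discrete genotypes, minor
#' allele frequency 0.2), and each trait vector is converted into a
#' [ks_feature_vector()] against the bank. The default design yields
#' `7 * 4 * 50 = 1400` labelled feature vectors.
#'
#' @param n sample size of each simulated trait (default 300).
#' @param samples_per_cell feature vectors per class-configuration cell
#'   (default 50).
#' @param bank a [reference_bank()].
#' @param ref_size reference sample size per density.
#' @param beta,log_alpha non-zero values used in the effect configurations.
#' @param seed master seed; every cell replicate draws from its own
#'   sub-stream.
#' @return list with `features` (matrix, rows = examples), `labels`
#'   (factor over the 7 classes) and `config` (data.frame of generating
#'   effects per example).
#' @export
build_training_set <- function(n = 300L, samples_per_cell = 50L,
                               bank = reference_bank(), ref_size = 100L,
                               beta = 0.5, log_alpha = 0.2, seed = 1L) {
  if (samples_per_cell < 1) stopf("invalid-argument: samples_per_cell must be >= 1")
  cells <- expand.grid(beta = c(0, beta), log_alpha = c(0, log_alpha),
                       KEEP.OUT.ATTRS = FALSE)
  total <- length(CLASS_LABELS) * nrow(cells) * samples_per_cell
  feats <- matrix(NA_real_, total, length(bank))
  labels <- character(total)
  cfg <- data.frame(beta = numeric(total), log_alpha = numeric(total))
  k <- 0L
  counter <- 0L
  for (lab in CLASS_LABELS) {
    for (ci in seq_len(nrow(cells))) {
      for (r in seq_len(samples_per_cell)) {
        k <- k + 1L
        s <- seed_stream(seed, counter)
        counter <- counter + 1L
        x <- simulate_discrete_genotypes(n, 0.2, seed = seed_stream(s, 0L))
        y <- simulate_class_trait(lab, x, cells$beta[ci], cells$log_alpha[ci],
                                  seed = seed_stream(s, 1L))
        feats[k, ] <- ks_feature_vector(y, bank, ref_size,
                                        seed = seed_stream(s, 2L))
        labels[k] <- lab
        cfg$beta[k] <- cells$beta[ci]
        cfg$log_alpha[k] <- cells$log_alpha[ci]
      }
    }
  }
  colnames(feats) <- attr(bank, "ids")
  list(features = feats, labels = factor(labels, levels = CLASS_LABELS),
       config = cfg)
}

#' Train the trait-distribution classifier
#'
#' Fits a random forest over KS feature vectors and reports k-fold
#' cross-validated performance (per-class precision and recall, macro
#' accuracy and the confusion matrix). Folds are stratified by class and
#' deterministic under `seed`.
#'
#' @param training a training set from [build_training_set()].
#' @param folds number of cross-validation folds (default 5).
#' @param ntree random forest size.
#' @param seed integer seed for fold assignment and forest fitting.
#' @return an object of class `dist_classifier`: list with `model` (the
#'   forest fitted on all data), `cv` (data.frame of per-class precision and
#'   recall), `macro_accuracy`, `confusion` and `bank_ids`.
#' @export
train_classifier <- function(training, folds = 5L, ntree = 300L, seed = 1L) {
  labels <- training$labels
  feats <- training$features
  if (any(table(labels) < 2)) {
    stopf("invalid-argument: every class needs at least 2 training examples")
  }
  with_seed(seed, {
    fold_of <- integer(length(labels))
    for (lab in levels(labels)) {
      idx <- sample(which(labels == lab))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      rf <- randomForest::randomForest(feats[tr, , drop = FALSE], labels[tr],
                                       ntree = ntree)
      pred[!tr] <- stats::predict(rf, feats[!tr, , drop = FALSE])
    }
    confusion <- table(truth = labels, predicted = pred)
    per_class <- do.call(rbind, lapply(levels(labels), function(lab) {
      tp <- confusion[lab, lab]
      data.frame(class = lab,
                 precision = tp / max(1, sum(confusion[, lab])),
                 recall = tp / max(1, sum(confusion[lab, ])))
    }))
    model <- randomForest::randomForest(feats, labels, ntree = ntree)
    structure(
      list(model = model, cv = per_class,
           macro_accuracy = mean(pred == labels),
           confusion = confusion,
           bank_ids = colnames(feats)),
      class = "dist_classifier")
  })
}

#' @export
print.dist_classifier <- function(x, ...) {
  cat(sprintf("<dist_classifier> %d classes, CV macro accuracy %.3f\n",
              nrow(x$cv), x$macro_accuracy))
  invisible(x)
}

#' Classify a trait and recommend a transformation
#'
#' Computes the KS feature vector of the trait against the bank, predicts
#' class probabilities with the trained forest, and maps the top class to
#' its prescriptive transformation (log for `log_gaussian`, mean-centred
#' square root for `gamma`, none otherwise).
#'
#' @param y trait vector.
#' @param x covariate vector (currently informational; features are
#'   computed on the pooled trait by default).
#' @param classifier a [train_classifier()] fit.
#' @param bank the [reference_bank()] the classifier was trained with.
#' @param ref_size reference sample size per density.
#' @param seed integer seed for the feature draw.
#' @return list with `probabilities` (named, summing to 1), `label` and
#'   `transform` (a [transform_spec()]).
#' @export
classify_and_recommend <- function(y, x = NULL, classifier,
                                   bank = reference_bank(), ref_size = 100L,
                                   seed = 1L) {
  stopifnot(inherits(classifier, "dist_classifier"))
  feats <- ks_feature_vector(y, bank, ref_size, seed = seed)
  if (!identical(names(feats), classifier$bank_ids)) {
    stopf("invalid-argument: bank does not match the classifier's bank")
  }
  prob <- stats::predict(classifier$model, t(feats), type = "prob")[1, ]
  label <- names(prob)[which.max(prob)]
  list(probabilities = prob, label = label,
       transform = recommend_transformation(label))
}
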