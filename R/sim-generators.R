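#' Simulate discrete biallelic genotypes
#'
#' Each sample's genotype is the number of copies of the minor allele from
#' two independent Bernoulli draws with success probability `pi_maf`, i.e.
#' an independent Binomial(2, pi_maf) draw per sample.
#'
#' @param n sample count (>= 1).
#' @param pi_maf minor allele frequency in \[0, 1\].
#' @param seed optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return integer vector of length `n` over \{0, 1, 2\}.
#' @export
#' @examples
#' table(simulate_discrete_genotypes(1000, 0.2, seed = 1))
simulate_discrete_genotypes <- function(n, pi_maf, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stopf("invalid-argument: n must be >= 1")
  }
  if (pi_maf < 0 || pi_maf > 1) stopf("invalid-argument: pi_maf must lie in [0, 1]")
  with_seed(seed, stats::rbinom(n, size = 2L, prob = pi_maf))
}

#' Simulate imputed genotype dosages
#'
#' Continuous covariates resembling imputed genotype dosages. A latent
#' genotype `z ~ Binomial(2, pi_maf)` is drawn per sample and the dosage is
#' `|c0|` when `z = 0`, `c1` when `z = 1` and `2 - |c2|` when `z = 2`, with
#' `c0, c2 ~ N(0, 0.5)` and `c1 ~ N(1, 0.5)`. The second parameter of these
#' normals is interpreted as the *variance* (sd = sqrt(0.5)); this is a
#' documented convention. Outputs are clipped to \[0, 2\] (the middle
#' component is unbounded); the number of clipped values is reported at
#' debug log level.
#'
#' @inheritParams simulate_discrete_genotypes
#' @return numeric vector of length `n` in \[0, 2\].
#' @export
simulate_imputed_genotypes <- function(n, pi_maf, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stopf("invalid-argument: n must be >= 1")
  }
  if (pi_maf < 0 || pi_maf > 1) stopf("invalid-argument: pi_maf must lie in [0, 1]")
  with_seed(seed, {
    z <- stats::rbinom(n, 2L, pi_maf)
    sdv <- sqrt(0.5)
    x <- numeric(n)
    x[z == 0L] <- abs(stats::rnorm(sum(z == 0L), 0, sdv))
    x[z == 1L] <- stats::rnorm(sum(z == 1L), 1, sdv)
    x[z == 2L] <- 2 - abs(stats::rnorm(sum(z == 2L), 0, sdv))
    n_clip <- sum(x < 0 | x > 2)
    if (n_clip > 0) hv_log("debug", "clipped %d dosage value(s) to [0, 2]", n_clip)
    pmin(2, pmax(0, x))
  })
}

#' Simulate a trait under the ideal heteroskedastic model
#'
#' Draws `y_i ~ N(beta0 + beta * x_i, sigma2 * alpha^(-x_i))` independently,
#' with `alpha = exp(log_alpha)`. At `log_alpha = 0` the trait is
#' homoskedastic; positive `log_alpha` shrinks the variance as the covariate
#' increases.
#'
#' @param x covariate vector.
#' @param config a [sim_config()] (only the trait parameters are used; the
#'   family must be `"ideal"`).
#' @param seed optional integer seed.
#' @return numeric trait vector of `length(x)`.
#' @export
simulate_trait_ideal <- function(x, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$family != "ideal") stopf("invalid-argument: config$family must be 'ideal'")
  if (config$sigma2 <= 0) stopf("invalid-argument: sigma2 must be > 0")
  mu <- config$beta0 + config$beta * x
  sdv <- sqrt(config$sigma2) * exp(-config$log_alpha * x / 2)
  with_seed(seed, stats::rnorm(length(x), mean = mu, sd = sdv))
}

#' Simulate a trait under one of the non-ideal models
#'
#' Four trait families that depart from the ideal heteroskedastic model (see
#' [sim_config()] for their definitions): additive variance, log Gaussian,
#' gamma, and a bimodal Gaussian mixture. The log-Gaussian trait is by
#' construction the elementwise exponential of an ideal-model draw under the
#' same seed.
#'
#' @inheritParams simulate_trait_ideal
#' @return numeric trait vector of `length(x)`.
#' @export
simulate_trait_nonideal <- function(x, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fam <- config$family
  if (!fam %in% c("additive_variance", "log_gaussian", "gamma", "bimodal")) {
    stopf("invalid-argument: family '%s' is not a non-ideal family", fam)
  }
  n <- length(x)
  switch(fam,
    additive_variance = {
      v <- config$sigma2 + config$log_alpha * x  # log_alpha holds the additive coefficient
      if (any(v <= 0)) {
        stopf("invalid-argument: additive variance sigma2 + a*x_i <= 0 for some i")
      }
      mu <- config$beta0 + config$beta * x
      with_seed(seed, stats::rnorm(n, mu, sqrt(v)))
    },
    log_gaussian = {
      ideal_cfg <- config
      ideal_cfg$family <- "ideal"
      exp(simulate_trait_ideal(x, ideal_cfg, seed = seed))
    },
    gamma = {
      lp <- config$beta0 + config$beta * x
      if (any(lp <= 0)) {
        stopf("invalid-argument: gamma family requires beta0 + beta*x_i > 0 for every i")
      }
      mu <- 1 / lp
      # Gamma(mu_i, 1) = shape mu_i, scale 1: mean and variance both mu_i,
      # the continuous analogue of overdispersed Poisson counts (for which
      # the square root is the classical variance-stabilizing transform)
      with_seed(seed, stats::rgamma(n, shape = mu, scale = 1))
    },
    bimodal = {
      mu <- config$beta0 + config$beta * x
      sdv <- sqrt(config$sigma2) * exp(-config$log_alpha * x / 2)
      with_seed(seed, {
        u <- stats::runif(n)
        spike <- stats::rnorm(n, 10, 1)
        base <- stats::rnorm(n, mu, sdv)
        ifelse(u < config$lambda_mix, spike, base)
      })
    })
}

# Covariate draw for a configuration.
simulate_covariate <- function(config, seed = NULL) {
  switch(config$covariate_kind,
    discrete = simulate_discrete_genotypes(config$n, config$pi_maf, seed),
    imputed = simulate_imputed_genotypes(config$n, config$pi_maf, seed),
    binary = with_seed(seed, stats::rbinom(config$n, 1L, config$pi_maf)),
    continuous = with_seed(seed, stats::runif(config$n, 0, 2)))
}

#' Simulate one covariate/trait dataset
#'
#' Draws the covariate according to `config$covariate_kind` and the trait
#' according to `config$family`, and labels the dataset with its hypothesis
#' class.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (falls back to `config$seed`).
#' @return an object of class `sim_dataset`: a list with components `x`,
#'   `y`, `truth` (the config), `hypothesis_class` and
#'   `is_permutation_null`.
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  x_seed <- if (is.null(seed)) NULL else seed_stream(seed, 0L)
  y_seed <- if (is.null(seed)) NULL else seed_stream(seed, 1L)
  x <- simulate_covariate(config, x_seed)
  y <- if (config$family == "ideal") {
    simulate_trait_ideal(x, config, y_seed)
  } else {
    simulate_trait_nonideal(x, config, y_seed)
  }
  structure(
    list(x = x, y = y, truth = config,
         hypothesis_class = hypothesis_class(config),
         is_permutation_null = FALSE),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> n=%d family=%s class=%s%s\n",
              length(x$y), x$truth$family, x$hypothesis_class,
              if (x$is_permutation_null) " (permutation null)" else ""))
  invisible(x)
}

#' Generate a benchmarking suite of simulated datasets
#'
#' For each configuration, `reps` datasets are generated and each is paired
#' with one mean-effect-preserving permutation null (see
#' [mean_preserving_permutation()]), flagged `is_permutation_null`. With one
#' configuration and `reps = 1000` this yields the canonical suite of 2000
#' tests, half from the permutation null. The suite is deterministic under
#' `seed`: every dataset derives its own sub-stream seed from a counter, so
#' results do not depend on generation order.
#'
#' @param configs a [sim_config()] or list of them.
#' @param reps number of replicate datasets per configuration (>= 1).
#' @param seed master seed.
#' @return list of `sim_dataset` objects, of length `2 * reps *
#'   length(configs)`; each real dataset is immediately followed by its
#'   permutation null.
#' @export
generate_benchmark_suite <- function(configs, reps, seed = 1L) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1, all(vapply(configs, inherits, TRUE, "sim_config")))
  if (!is.numeric(reps) || reps < 1) stopf("invalid-argument: reps must be >= 1")
  out <- vector("list", 2L * reps * length(configs))
  k <- 0L
  counter <- 0L
  for (cfg in configs) {
    for (r in seq_len(reps)) {
      ds <- simulate_dataset(cfg, seed = seed_stream(seed, counter))
      perm_y <- mean_preserving_permutation(ds$y, ds$x,
                                            seed = seed_stream(seed, counter + 1L))
      null_ds <- ds
      null_ds$y <- as.numeric(perm_y)
      null_ds$is_permutation_null <- TRUE
      out[[k + 1L]] <- ds
      out[[k + 2L]] <- null_ds
      k <- k + 2L
      counter <- counter + 2L
    }
  }
  out
}

#' Write / read a benchmark suite as TSV files
#'
#' `write_benchmark_suite()` writes three tab-delimited files under `dir`:
#' `traits.tsv` (rows = replicate IDs, columns = sample IDs),
#' `covariates.tsv` (likewise) and `manifest.tsv` with one row per replicate
#' giving every generating parameter, the hypothesis class and the
#' permutation-null flag. `read_benchmark_suite()` inverts it.
#'
#' All datasets in one suite must share a common sample count.
#'
#' @param suite list of `sim_dataset` objects.
#' @param dir output directory (created if missing).
#' @return `write_benchmark_suite()` returns `dir` invisibly;
#'   `read_benchmark_suite()` returns the list of datasets.
#' @export
write_benchmark_suite <- function(suite, dir) {
  stopifnot(length(suite) >= 1)
  ns <- vapply(suite, function(d) length(d$y), 1L)
  if (length(unique(ns)) != 1L) {
    stopf("invalid-argument: all datasets in a suite must share one sample count")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- sprintf("rep%05d", seq_along(suite))
  samples <- sprintf("s%04d", seq_len(ns[1]))
  ymat <- do.call(rbind, lapply(suite, `[[`, "y"))
  xmat <- do.call(rbind, lapply(suite, `[[`, "x"))
  rownames(ymat) <- rownames(xmat) <- ids
  colnames(ymat) <- colnames(xmat) <- samples
  write_trait_matrix(ymat, file.path(dir, "traits.tsv"))
  write_trait_matrix(xmat, file.path(dir, "covariates.tsv"))
  manifest <- do.call(rbind, lapply(seq_along(suite), function(i) {
    tr <- suite[[i]]$truth
    data.frame(replicate_id = ids[i], n = tr$n, pi_maf = tr$pi_maf,
               beta0 = tr$beta0, beta = tr$beta, sigma2 = tr$sigma2,
               log_alpha = tr$log_alpha, family = tr$family,
               lambda_mix = tr$lambda_mix,
               covariate_kind = tr$covariate_kind,
               hypothesis_class = suite[[i]]$hypothesis_class,
               is_permutation_null = suite[[i]]$is_permutation_null)
  }))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_benchmark_suite
#' @export
read_benchmark_suite <- function(dir) {
  ymat <- read_trait_matrix(file.path(dir, "traits.tsv"))
  xmat <- read_trait_matrix(file.path(dir, "covariates.tsv"))
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    cfg <- sim_config(n = m$n, pi_maf = m$pi_maf, beta0 = m$beta0,
                      beta = m$beta, sigma2 = m$sigma2,
                      log_alpha = m$log_alpha, family = m$family,
                      lambda_mix = m$lambda_mix,
                      covariate_kind = m$covariate_kind)
    structure(
      list(x = as.numeric(xmat[m$replicate_id, ]),
           y = as.numeric(ymat[m$replicate_id, ]),
           truth = cfg,
           hypothesis_class = m$hypothesis_class,
           is_permutation_null = m$is_permutation_null),
      class = "sim_dataset")
  })
}
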