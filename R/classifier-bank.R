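# Reference density bank for the trait-distribution classifier.
#
# Every entry samples from a density standardized to mean 0 and variance 1
# (analytically, so moment matching to a query sample is an exact
# location-scale transform).  The default bank spans 79 shapes: Gaussian,
# Student-t over df, lognormal over sdlog, gamma over shape, beta over
# (a, b), uniform, Laplace, and two-component Gaussian mixtures over a
# weight x separation grid.

bank_entry <- function(id, sampler) list(id = id, sampler = sampler)

std_t <- function(df) function(n) stats::rt(n, df) / sqrt(df / (df - 2))

std_lnorm <- function(sdlog) {
  m <- exp(sdlog^2 / 2)
  s <- sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
  function(n) (stats::rlnorm(n, 0, sdlog) - m) / s
}

std_gamma <- function(shape) function(n) (stats::rgamma(n, shape, rate = 1) - shape) / sqrt(shape)

std_beta <- function(a, b) {
  m <- a / (a + b)
  s <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  function(n) (stats::rbeta(n, a, b) - m) / s
}

std_mixture <- function(w, delta) {
  # components N(mu1, 1), N(mu2, 1) with overall mean 0, separation delta
  mu1 <- -(1 - w) * delta
  mu2 <- w * delta
  s <- sqrt(1 + w * (1 - w) * delta^2)
  function(n) {
    z <- stats::rbinom(n, 1L, w)
    (stats::rnorm(n, ifelse(z == 1L, mu1, mu2), 1)) / s
  }
}

#' Reference density bank
#'
#' A bank of `R` standardized reference densities against which a query
#' trait sample is compared by one-sided Kolmogorov-Smirnov statistics (see
#' [ks_feature_vector()]). Each density can generate samples of any size
#' with population mean 0 and variance 1; moment matching to a query is a
#' location-scale transform to the query's sample mean and variance. The
#' default bank contains exactly 79 densities: Gaussian (1), Student-t over
#' 12 df values, lognormal over 10 sdlog values, gamma over 10 shapes, beta
#' over 12 shape pairs, uniform (1), Laplace (1) and 32 two-component
#' Gaussian mixtures over a weight-by-separation grid. The identity of the
#' densities is configurable; the classifier contract depends only on the
#' bank size and moment matching.
#'
#' @param entries optional list of entries (each a list with `id` and
#'   `sampler(n)`) replacing the default bank.
#' @return an object of class `reference_bank` (a list of entries with
#'   attribute `ids`).
#' @export
#' @examples
#' bank <- reference_bank()
#' length(bank)  # 79
reference_bank <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- c(
      list(bank_entry("gaussian", function(n) stats::rnorm(n))),
      lapply(c(3, 4, 5, 6, 7, 8, 10, 12, 15, 20, 25, 30), function(df)
        bank_entry(sprintf("t_df%g", df), std_t(df))),
      lapply(seq(0.1, 1.0, by = 0.1), function(s)
        bank_entry(sprintf("lognormal_sd%.1f", s), std_lnorm(s))),
      lapply(c(0.5, 1, 1.5, 2, 3, 4, 5, 7, 10, 15), function(k)
        bank_entry(sprintf("gamma_shape%g", k), std_gamma(k))),
      {
        ab <- list(c(0.5, 0.5), c(2, 2), c(5, 5), c(1, 3), c(3, 1),
                   c(2, 5), c(5, 2), c(0.5, 2), c(2, 0.5), c(1, 5),
                   c(5, 1), c(0.5, 5))
        lapply(ab, function(p)
          bank_entry(sprintf("beta_%g_%g", p[1], p[2]), std_beta(p[1], p[2])))
      },
      list(bank_entry("uniform", function(n) (stats::runif(n) - 0.5) * sqrt(12)),
           bank_entry("laplace", function(n)
             (stats::rexp(n) - stats::rexp(n)) / sqrt(2))),
      {
        grid <- expand.grid(w = c(0.2, 0.35, 0.5, 0.65),
                            delta = c(1, 2, 3, 4, 5, 6, 7, 8))
        lapply(seq_len(nrow(grid)), function(i)
          bank_entry(sprintf("mix_w%.2f_d%g", grid$w[i], grid$delta[i]),
                     std_mixture(grid$w[i], grid$delta[i])))
      })
  }
  ids <- vapply(entries, `[[`, "", "id")
  if (anyDuplicated(ids)) stopf("invalid-argument: duplicate bank identifiers")
  structure(entries, ids = ids, class = "reference_bank")
}

#' @export
print.reference_bank <- function(x, ...) {
  cat(sprintf("<reference_bank> %d densities\n", length(x)))
  invisible(x)
}

# One-sided (D+) two-sample KS statistic: sup_t ECDF_query(t) - ECDF_ref(t).
ks_dplus <- function(query, ref) {
  tt <- sort(c(query, ref))
  fq <- findInterval(tt, sort(query)) / length(query)
  fr <- findInterval(tt, sort(ref)) / length(ref)
  max(fq - fr)
}

#' One-sided KS feature vector against the reference bank
#'
#' Represents a trait sample as a point in `length(bank)`-dimensional
#' feature space: for each reference density, `ref_size` moment-matched
#' samples are drawn (location-scale adjusted to the query's sample mean and
#' variance) and the one-sided Kolmogorov-Smirnov statistic `D+ = sup_t
#' (ECDF_query(t) - ECDF_ref(t))` is recorded. Deterministic under `seed`.
#'
#' @param sample query trait vector, at least 20 values with non-zero
#'   variance.
#' @param bank a [reference_bank()].
#' @param ref_size reference sample size per density (default 100).
#' @param seed optional integer seed.
#' @return named numeric vector of length `length(bank)`.
#' @export
ks_feature_vector <- function(sample, bank = reference_bank(),
                              ref_size = 100L, seed = NULL) {
  if (length(sample) < 20) stopf("invalid-argument: need at least 20 query values")
  s2 <- stats::var(sample)
  if (s2 == 0) stopf("invalid-argument: query sample has zero variance")
  m <- mean(sample)
  s <- sqrt(s2)
  with_seed(seed, {
    feats <- vapply(bank, function(e) {
      ks_dplus(sample, e$sampler(ref_size) * s + m)
    }, 1)
    names(feats) <- attr(bank, "ids")
    feats
  })
}
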