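#' Simulation configuration for covariate/trait generation
#'
#' Bundles the generating parameters of one simulation scenario: the sample
#' size, the covariate model (minor allele frequency and kind) and the trait
#' model (intercept, mean effect, residual variance, heteroskedastic effect
#' and trait family).
#'
#' The trait families are:
#' \describe{
#'   \item{`ideal`}{`y_i ~ N(beta0 + beta * x_i, sigma2 * alpha^(-x_i))` with
#'     `alpha = exp(log_alpha)`; the model the Bayesian heteroskedasticity
#'     test assumes.}
#'   \item{`additive_variance`}{`y_i ~ N(beta0 + beta * x_i,
#'     sigma2 + a * x_i)`. For this family the `log_alpha` field is read
#'     directly as the additive variance coefficient `a`, whose null value is
#'     0 — so `log_alpha = 0` means "no variance effect" for every family.}
#'   \item{`log_gaussian`}{`y = exp(z)` where `z` is an ideal-model draw.}
#'   \item{`gamma`}{`y_i ~ Gamma(shape = mu_i, scale = 1)` with
#'     `mu_i = 1 / (beta0 + beta*x_i)`, so mean and variance both equal
#'     `mu_i` — the continuous analogue of overdispersed Poisson counts;
#'     requires `beta0 + beta*x_i > 0` for every generated `x_i`. The
#'     variance is tied to the mean, so there is no separate variance-effect
#'     parameter, and the square root is its variance-stabilizing
#'     transformation.}
#'   \item{`bimodal`}{with probability `lambda_mix` a draw from `N(10, 1)`,
#'     otherwise an ideal-model draw.}
#' }
#'
#' @param n sample count (at least 4).
#' @param pi_maf minor allele frequency in (0, 1) (degenerate values 0 and 1
#'   are allowed only by the raw genotype samplers, not by `sim_config()`).
#' @param beta0 intercept.
#' @param beta mean effect size.
#' @param sigma2 residual variance, strictly positive. Default 1.
#' @param log_alpha heteroskedastic effect on the log scale (additive
#'   variance coefficient for the `additive_variance` family).
#' @param family trait family, see Details.
#' @param lambda_mix mixture weight in \[0, 1\] for the `bimodal` family.
#' @param covariate_kind one of `"discrete"` (genotypes in \{0,1,2\}),
#'   `"imputed"` (dosages in \[0,2\]), `"binary"` (\{0,1\}) or
#'   `"continuous"` (uniform on \[0,2\], an age/BMI-like covariate).
#' @param seed optional integer seed attached to the configuration.
#' @return an object of class `sim_config`.
#' @seealso [simulate_dataset()], [generate_benchmark_suite()]
#' @export
#' @examples
#' cfg <- sim_config(n = 300, pi_maf = 0.2, beta = 0.5, log_alpha = 0.1)
#' hypothesis_class(cfg)
sim_config <- function(n, pi_maf = 0.2, beta0 = 0, beta = 0, sigma2 = 1,
                       log_alpha = 0,
                       family = c("ideal", "additive_variance", "log_gaussian",
                                  "gamma", "bimodal"),
                       lambda_mix = 0.4,
                       covariate_kind = c("discrete", "imputed", "binary",
                                          "continuous"),
                       seed = NULL) {
  family <- match.arg(family)
  covariate_kind <- match.arg(covariate_kind)
  if (!is.numeric(n) || length(n) != 1L || n < 4) {
    stopf("invalid-argument: n must be a single number >= 4, got %s",
          deparse(n))
  }
  if (!is.numeric(pi_maf) || pi_maf <= 0 || pi_maf >= 1) {
    stopf("invalid-argument: pi_maf must lie strictly in (0, 1)")
  }
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stopf("invalid-argument: sigma2 must be > 0")
  }
  if (lambda_mix < 0 || lambda_mix > 1) {
    stopf("invalid-argument: lambda_mix must lie in [0, 1]")
  }
  if (family == "gamma") {
    # the support of x is [0, 2] for every covariate kind
    if (beta0 + beta * 0 <= 0 || beta0 + beta * 2 <= 0) {
      stopf("invalid-argument: gamma family requires beta0 + beta*x > 0 over x in [0, 2]")
    }
  }
  if (family == "additive_variance" && sigma2 + log_alpha * 2 <= 0) {
    stopf("invalid-argument: additive variance sigma2 + a*x must stay positive over x in [0, 2]")
  }
  structure(
    list(n = as.integer(n), pi_maf = pi_maf, beta0 = beta0, beta = beta,
         sigma2 = sigma2, log_alpha = log_alpha, family = family,
         lambda_mix = lambda_mix, covariate_kind = covariate_kind,
         seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> family=%s kind=%s n=%d pi_maf=%.3g beta0=%.3g beta=%.3g sigma2=%.3g log_alpha=%.3g\n",
    x$family, x$covariate_kind, x$n, x$pi_maf, x$beta0, x$beta, x$sigma2,
    x$log_alpha))
  invisible(x)
}

#' Hypothesis class of a simulation scenario
#'
#' Classifies a (mean effect, variance effect) pair into the four-way
#' taxonomy used to interpret test behaviour under model misspecification:
#' strong null (no mean, no variance effect), weak null (mean effect only),
#' weak alternative (variance effect only) and strong alternative (both).
#'
#' @param config a [sim_config()] object, or a numeric `beta` when
#'   `log_alpha` is given.
#' @param log_alpha variance effect, used when `config` is a bare `beta`.
#' @return one of `"strong_null"`, `"weak_null"`, `"weak_alternative"`,
#'   `"strong_alternative"`.
#' @export
hypothesis_class <- function(config, log_alpha = NULL) {
  if (inherits(config, "sim_config")) {
    beta <- config$beta
    log_alpha <- config$log_alpha
  } else {
    beta <- config
    if (is.null(log_alpha)) stopf("invalid-argument: log_alpha missing")
  }
  if (beta == 0 && log_alpha == 0) "strong_null"
  else if (beta != 0 && log_alpha == 0) "weak_null"
  else if (beta == 0 && log_alpha != 0) "weak_alternative"
  else "strong_alternative"
}

#' Default simulation parameter grid
#'
#' The full factorial grid of generating parameters used throughout the
#' simulation studies: `n` in \{300, 500, 1000\}, minor allele frequency in
#' \{0.05, 0.2, 0.3\}, mean effect `beta` in \{0, 0.2, 0.5, 1\},
#' heteroskedastic effect `log_alpha` in \{-0.2, -0.1, 0, 0.1, 0.2\},
#' intercept `beta0` in \{0, 1\} and fixed `sigma2 = 1`.
#'
#' @return a data.frame with one row per parameter configuration.
#' @export
default_parameter_grid <- function() {
  expand.grid(n = c(300L, 500L, 1000L),
              pi_maf = c(0.05, 0.2, 0.3),
              beta = c(0, 0.2, 0.5, 1),
              log_alpha = c(-0.2, -0.1, 0, 0.1, 0.2),
              beta0 = c(0, 1),
              sigma2 = 1,
              KEEP.OUT.ATTRS = FALSE)
}
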