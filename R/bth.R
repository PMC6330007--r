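#' Hyperparameters of the Bayesian heteroskedasticity test
#'
#' Priors of the heteroskedastic linear model
#' `y_i ~ N(beta0 + beta * x_i, sigma2 * alpha^(-x_i))`:
#' a flat (improper) prior on the intercept `beta0`, a Gaussian prior
#' `beta ~ N(0, 1/beta_prior_precision)` on the mean effect, an inverse-gamma
#' prior `sigma2 ~ InvGamma(theta1, theta2)` on the residual variance, and a
#' Cauchy prior `log(alpha) ~ Cauchy(x0, nu)` on the heteroskedastic effect.
#' The flat intercept prior is shared by the numerator and denominator of the
#' Bayes factor, so its (improper) normalizing constant cancels; individual
#' marginal likelihoods returned by [laplace_log_marginal()] are therefore
#' only defined up to that shared constant and should never be interpreted as
#' calibrated on their own.
#'
#' @param x0 Cauchy location of the `log(alpha)` prior. Default 0, centring
#'   the prior on "no variance effect".
#' @param nu Cauchy scale, > 0. Default 5.
#' @param theta1 inverse-gamma shape, > 0. Default 1.
#' @param theta2 inverse-gamma scale, > 0. Default 2.
#' @param beta_prior_precision prior precision of the mean effect, > 0.
#'   Default 1.
#' @return an object of class `bth_hyper`.
#' @export
bth_hyperparams <- function(x0 = 0, nu = 5, theta1 = 1, theta2 = 2,
                            beta_prior_precision = 1) {
  if (nu <= 0 || theta1 <= 0 || theta2 <= 0 || beta_prior_precision <= 0) {
    stopf("invalid-argument: all scale hyperparameters must be strictly positive")
  }
  structure(list(x0 = x0, nu = nu, theta1 = theta1, theta2 = theta2,
                 beta_prior_precision = beta_prior_precision),
            class = "bth_hyper")
}

log_dinvgamma <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Log marginal likelihood with the mean effect integrated out
#'
#' Computes `log integral N(y | beta0 + beta*x, diag(sigma2 * alpha^(-x_i)))
#' N(beta | 0, 1/gamma) dbeta` in closed form via Gaussian conjugacy, with
#' observation weights `w_i = alpha^(x_i) / sigma2`. This is the only exact
#' integral in the Bayes factor; the remaining parameters are handled by the
#' Laplace approximation in [laplace_log_marginal()].
#'
#' @param y trait vector.
#' @param x covariate vector, same length as `y` (>= 4).
#' @param beta0 intercept value.
#' @param sigma2 residual variance, > 0.
#' @param log_alpha heteroskedastic effect on the log scale.
#' @param hyper a [bth_hyperparams()] object.
#' @return the log marginal likelihood (a finite scalar for finite inputs).
#' @export
log_marginal_beta_integrated <- function(y, x, beta0, sigma2, log_alpha,
                                         hyper = bth_hyperparams()) {
  n <- length(y)
  if (length(x) != n) stopf("invalid-argument: length(y) != length(x)")
  if (n < 4) stopf("invalid-argument: need at least 4 samples")
  if (sigma2 <= 0) stopf("invalid-argument: sigma2 must be > 0")
  gam <- hyper$beta_prior_precision
  log_w <- log_alpha * x - log(sigma2)
  w <- exp(log_w)
  r <- y - beta0
  prec <- gam + sum(w * x * x)
  b <- sum(w * x * r)
  -n / 2 * log(2 * pi) + sum(log_w) / 2 + log(gam) / 2 - log(prec) / 2 -
    sum(w * r * r) / 2 + b * b / (2 * prec)
}

# Objective g(par) whose exponential is Laplace-integrated: the
# beta-marginalized likelihood plus the log priors of sigma2 (with the
# sigma2 -> log sigma2 Jacobian) and, when alpha is free, of log alpha.
bth_objective <- function(par, y, x, hyper, alpha_free) {
  beta0 <- par[1L]
  ls <- par[2L]
  la <- if (alpha_free) par[3L] else 0
  if (!all(is.finite(par)) || abs(ls) > 700 || abs(la) > 700) return(-Inf)
  sigma2 <- exp(ls)
  val <- log_marginal_beta_integrated(y, x, beta0, sigma2, la, hyper) +
    log_dinvgamma(sigma2, hyper$theta1, hyper$theta2) + ls
  if (alpha_free) {
    val <- val + stats::dcauchy(la, hyper$x0, hyper$nu, log = TRUE)
  }
  val
}

fd_gradient <- function(fn, par, h_rel = 1e-6) {
  d <- length(par)
  g <- numeric(d)
  for (j in seq_len(d)) {
    h <- h_rel * max(1, abs(par[j]))
    up <- dn <- par
    up[j] <- par[j] + h
    dn[j] <- par[j] - h
    g[j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  g
}

# Central finite-difference Hessian with per-coordinate step
# 1e-4 * max(1, |theta_j|).
fd_hessian <- function(fn, par, h_rel = 1e-4) {
  d <- length(par)
  h <- h_rel * pmax(1, abs(par))
  H <- matrix(0, d, d)
  f0 <- fn(par)
  for (j in seq_len(d)) {
    ej <- rep(0, d); ej[j] <- h[j]
    H[j, j] <- (fn(par + ej) - 2 * f0 + fn(par - ej)) / h[j]^2
    if (j < d) {
      for (k in (j + 1L):d) {
        ek <- rep(0, d); ek[k] <- h[k]
        H[j, k] <- H[k, j] <-
          (fn(par + ej + ek) - fn(par + ej - ek) -
             fn(par - ej + ek) + fn(par - ej - ek)) / (4 * h[j] * h[k])
      }
    }
  }
  H
}

#' Laplace approximation of the marginal likelihood
#'
#' Maximizes the beta-marginalized log posterior kernel over
#' `(beta0, log sigma2)` (null model, `alpha` fixed at 1) or
#' `(beta0, log sigma2, log alpha)` (alternative), then applies the Laplace
#' correction `log_marginal = g(mode) + d/2 * log(2*pi) - 1/2 * log
#' det(-Hessian)`. Optimization is quasi-Newton (BFGS) from deterministic
#' starting values (OLS intercept, log OLS residual variance, `log alpha =
#' 0`), followed by Newton polishing with a finite-difference Hessian; up to
#' three additional deterministic perturbed restarts are tried if the
#' gradient max-norm at the mode exceeds the convergence tolerance (1e-5 on
#' the scale of the objective). The whole procedure is deterministic, so
#' repeated calls return identical fits.
#'
#' @inheritParams log_marginal_beta_integrated
#' @param alpha_free logical; `FALSE` fixes `alpha = 1` (the point null).
#' @return an object of class `laplace_fit` with components `mode` (named
#'   vector), `log_det_hessian` (log |det(-H)|), `log_marginal`,
#'   `converged`, `iterations` and `grad_max_norm`.
#' @export
laplace_log_marginal <- function(y, x, hyper = bth_hyperparams(),
                                 alpha_free = TRUE) {
  n <- length(y)
  if (length(x) != n) stopf("invalid-argument: length(y) != length(x)")
  if (n < 4) stopf("invalid-argument: need at least 4 samples")
  if (stats::var(x) == 0) stopf("invalid-argument: covariate has zero variance")
  fn <- function(p) bth_objective(p, y, x, hyper, alpha_free)

  ols <- stats::lm.fit(cbind(1, x), y)
  rv <- max(sum(ols$residuals^2) / max(1, n - 2), 1e-12)
  start <- c(ols$coefficients[1L], log(rv))
  if (alpha_free) start <- c(start, 0)
  d <- length(start)
  grad_tol <- 1e-5

  run_one <- function(st) {
    opt <- tryCatch(
      stats::optim(st, fn, method = "BFGS",
                   control = list(fnscale = -1, maxit = 200L,
                                  reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) return(NULL)
    mode <- opt$par
    iters <- opt$counts[["function"]]
    # Newton polish to drive the gradient toward zero
    for (i in 1:10) {
      g <- fd_gradient(fn, mode)
      if (max(abs(g)) <= grad_tol) break
      H <- fd_hessian(fn, mode)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- mode - step
      if (!is.finite(fn(cand)) || fn(cand) < fn(mode) - 1e-6) break
      mode <- cand
      iters <- iters + 1L
    }
    g <- fd_gradient(fn, mode)
    list(mode = mode, value = fn(mode), grad = max(abs(g)), iters = iters)
  }

  fit <- run_one(start)
  if (is.null(fit) || fit$grad > grad_tol) {
    perturb <- list(c(0.5, 0.5, 0.5), c(-0.5, -0.5, -0.5), c(1, -1, 1))
    for (p in perturb) {
      alt <- run_one(start + p[seq_len(d)])
      if (!is.null(alt) &&
          (is.null(fit) || alt$value > fit$value + 1e-8 ||
             (alt$grad < fit$grad && alt$value >= fit$value - 1e-6))) {
        fit <- alt
      }
      if (!is.null(fit) && fit$grad <= grad_tol) break
    }
  }
  if (is.null(fit)) stopf("numerical-failure: objective not finite at any start")

  H <- fd_hessian(fn, fit$mode)
  negH <- -H
  ch <- tryCatch(chol(negH), error = function(e) NULL)
  pd <- !is.null(ch)
  if (!pd) {
    # jitter toward positive definiteness; flags non-convergence
    jit <- max(abs(diag(negH))) * 1e-8 + 1e-10
    ch <- tryCatch(chol(negH + diag(jit, d)), error = function(e) NULL)
  }
  if (is.null(ch)) {
    ldet <- as.numeric(determinant(negH, logarithm = TRUE)$modulus)
  } else {
    ldet <- 2 * sum(log(diag(ch)))
  }
  mode <- fit$mode
  names(mode) <- c("beta0", "log_sigma2", if (alpha_free) "log_alpha")
  structure(
    list(mode = mode,
         log_det_hessian = ldet,
         log_marginal = fit$value + d / 2 * log(2 * pi) - ldet / 2,
         converged = pd && fit$grad <= grad_tol,
         iterations = fit$iters,
         grad_max_norm = fit$grad,
         alpha_free = alpha_free),
    class = "laplace_fit")
}

#' Bayes factor of the Bayesian heteroskedasticity test
#'
#' Compares the marginal likelihood of the trait under the alternative
#' (`alpha` free, with its Cauchy prior) against the point null
#' (`alpha = 1`), each computed by [laplace_log_marginal()], and reports the
#' base-10 log Bayes factor. Positive values favour a variance effect of the
#' covariate.
#'
#' @inheritParams log_marginal_beta_integrated
#' @return an object of class `bf_result`: a list with `log10_bf`,
#'   `fit_alt`, `fit_null` and `n`.
#' @export
#' @examples
#' x <- simulate_discrete_genotypes(200, 0.3, seed = 2)
#' cfg <- sim_config(n = 200, pi_maf = 0.3, beta = 0.5, log_alpha = 0.4)
#' y <- simulate_trait_ideal(x, cfg, seed = 3)
#' bth_bayes_factor(y, x)
bth_bayes_factor <- function(y, x, hyper = bth_hyperparams()) {
  if (length(y) != length(x)) stopf("invalid-argument: length(y) != length(x)")
  if (!all(is.finite(y)) || !all(is.finite(x))) {
    stopf("invalid-argument: non-finite values in y or x")
  }
  if (length(y) < 4) stopf("invalid-argument: need at least 4 samples")
  if (stats::var(x) == 0) stopf("invalid-argument: covariate has zero variance")
  if (stats::var(y) == 0) stopf("invalid-argument: trait has zero variance")
  fit_alt <- laplace_log_marginal(y, x, hyper, alpha_free = TRUE)
  fit_null <- laplace_log_marginal(y, x, hyper, alpha_free = FALSE)
  structure(
    list(log10_bf = (fit_alt$log_marginal - fit_null$log_marginal) / log(10),
         fit_alt = fit_alt, fit_null = fit_null, n = length(y)),
    class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<bth> log10 BF = %.4f (n = %d, converged: alt %s / null %s)\n",
              x$log10_bf, x$n, x$fit_alt$converged, x$fit_null$converged))
  cat(sprintf("  mode: beta0 = %.4f, sigma2 = %.4f, log_alpha = %.4f\n",
              x$fit_alt$mode[["beta0"]], exp(x$fit_alt$mode[["log_sigma2"]]),
              x$fit_alt$mode[["log_alpha"]]))
  invisible(x)
}
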