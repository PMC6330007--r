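# Comparison tests for heteroskedasticity, all returning a common
# `het_test` result contract.

het_test_result <- function(method, statistic = NA_real_, p_value = NULL,
                            log10_bf = NULL, df = NULL, converged = TRUE,
                            n = NA_integer_, extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value, log10_bf = log10_bf, df = df,
                   converged = converged, n = n), extra),
            class = "het_test")
}

#' @export
print.het_test <- function(x, ...) {
  if (!is.null(x$log10_bf)) {
    cat(sprintf("<het_test:%s> log10 BF = %.4f (n = %d)\n", x$method,
                x$log10_bf, x$n))
  } else {
    cat(sprintf("<het_test:%s> statistic = %.4f, p = %.4g (n = %d%s)\n",
                x$method, x$statistic, x$p_value, x$n,
                if (isTRUE(x$converged)) "" else ", NOT converged"))
  }
  invisible(x)
}

check_groups <- function(y, x) {
  g <- split(y, x)
  if (length(g) < 2) stopf("invalid-argument: covariate defines fewer than 2 groups")
  if (any(lengths(g) < 2)) {
    stopf("invalid-argument: every covariate group needs at least 2 observations")
  }
  g
}

#' Levene family test for equality of group variances
#'
#' The classical ANOVA-on-absolute-deviations statistic for k groups defined
#' by a categorical covariate:
#' `W = (n - k) * sum_t n_t * (zbar_t - zbar)^2 /
#'      [(k - 1) * sum_t sum_s (z_ts - zbar_t)^2]`,
#' where `z_ts = |omega_t(s) - center_t|` and `center_t` is the group mean
#' (Levene's test) or group median (the Brown-Forsythe variant, which is
#' robust to asymmetric noise). The p-value is taken from the
#' `F(k - 1, n - k)` reference distribution. If all absolute deviations are
#' equal within groups, the statistic is 0 with p-value 1 by convention, so
#' downstream FDR machinery never sees missing values.
#'
#' @param y trait vector.
#' @param x categorical covariate with k >= 2 levels, each with at least 2
#'   observations.
#' @param center `"mean"` (Levene) or `"median"` (Brown-Forsythe).
#' @return a `het_test` result with `statistic`, `p_value` and `df`.
#' @export
#' @examples
#' x <- rep(0:2, each = 50)
#' y <- rnorm(150, sd = c(1, 1.5, 2)[x + 1])
#' levene_family_test(y, x, center = "median")
levene_family_test <- function(y, x, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(y) != length(x)) stopf("invalid-argument: length(y) != length(x)")
  g <- check_groups(y, x)
  k <- length(g)
  n <- length(y)
  centre_fun <- if (center == "mean") mean else stats::median
  z <- lapply(g, function(v) abs(v - centre_fun(v)))
  zbar_t <- vapply(z, mean, 1)
  n_t <- lengths(z)
  zbar <- sum(unlist(z)) / n
  num <- sum(n_t * (zbar_t - zbar)^2)
  den <- sum(vapply(seq_len(k), function(t) sum((z[[t]] - zbar_t[t])^2), 1))
  if (den <= .Machine$double.eps * max(1, num)) {
    W <- 0
    p <- 1
  } else {
    W <- (n - k) * num / ((k - 1) * den)
    p <- stats::pf(W, k - 1, n - k, lower.tail = FALSE)
  }
  het_test_result(if (center == "mean") "levene" else "brown_forsythe",
                  statistic = W, p_value = p, df = c(k - 1, n - k), n = n)
}

#' Bartlett test for equality of group variances
#'
#' The pooled-variance chi-square test of equal group variances, which
#' assumes Gaussian groups and is therefore sensitive to departures from
#' normality; included for comparison with the Levene family.
#'
#' @inheritParams levene_family_test
#' @return a `het_test` result.
#' @export
bartlett_test <- function(y, x) {
  if (length(y) != length(x)) stopf("invalid-argument: length(y) != length(x)")
  g <- check_groups(y, x)
  if (any(vapply(g, stats::var, 1) == 0)) {
    stopf("numerical-failure: a covariate group has zero variance")
  }
  bt <- stats::bartlett.test(g)
  het_test_result("bartlett", statistic = unname(bt$statistic),
                  p_value = bt$p.value, df = unname(bt$parameter),
                  n = length(y))
}

# All permutations of 1..n as an n! x n matrix (used for exact Spearman
# p-values at small n only).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Correlation least squares (CLS) test
#'
#' Two-stage test for heteroskedasticity against a general (discrete or
#' continuous) covariate: fit `y = beta0 + beta * x` by least squares, then
#' test for Spearman rank correlation between the squared residuals and the
#' covariate (average ranks for ties). The p-value uses the t-distribution
#' approximation on n - 2 degrees of freedom for n >= 10 and the exact
#' permutation distribution for n < 10. If the squared residuals are all
#' tied (including the perfect-fit case), the statistic is 0 with p-value 1
#' by convention.
#'
#' @inheritParams levene_family_test
#' @param x covariate vector, non-constant, n >= 4.
#' @return a `het_test` result whose `statistic` is the Spearman rank
#'   correlation.
#' @export
cls_test <- function(y, x) {
  n <- length(y)
  if (length(x) != n) stopf("invalid-argument: length(y) != length(x)")
  if (n < 4) stopf("invalid-argument: need at least 4 samples")
  if (stats::var(x) == 0) stopf("invalid-argument: covariate has zero variance")
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- fit$residuals^2
  if (diff(range(r2)) <= 1e-10 * max(1, max(r2))) {
    return(het_test_result("cls", statistic = 0, p_value = 1,
                           df = n - 2, n = n))
  }
  a <- rank(r2, ties.method = "average")
  b <- rank(x, ties.method = "average")
  rho <- stats::cor(a, b)
  if (n < 10) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1L, function(p) stats::cor(a, b[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  het_test_result("cls", statistic = rho, p_value = p, df = n - 2, n = n)
}

# Gaussian log-likelihood with per-observation variances.
gaussian_loglik <- function(resid2, phi) {
  -0.5 * sum(log(2 * pi * phi) + resid2 / phi)
}

# One double-GLM fit: alternating weighted least squares for the mean and a
# gamma GLM (log link, prior weights 1/2) for the dispersion with linear
# predictor lambda0 [+ lambda1 * x].  Returns the fitted Gaussian
# log-likelihood, or NULL on failure.
dglm_fit <- function(y, x, dispersion_covariate, max_iter = 50L,
                     tol = 1e-8) {
  n <- length(y)
  X <- cbind(1, x)
  Zd <- if (dispersion_covariate) cbind(1, x) else matrix(1, n, 1)
  eps_floor <- .Machine$double.eps * max(1, stats::var(y))
  phi <- rep(stats::var(y), n)
  ll_old <- -Inf
  ll <- NA_real_
  converged <- FALSE
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    fit_m <- stats::lm.wfit(X, y, w = 1 / phi)
    d <- fit_m$residuals^2
    if (any(d < eps_floor)) {
      d <- pmax(d, eps_floor)
      floored <- TRUE
    }
    fit_d <- tryCatch(
      suppressWarnings(stats::glm.fit(
        Zd, d, weights = rep(0.5, n),
        family = stats::Gamma(link = "log"),
        control = stats::glm.control(maxit = 100L))),
      error = function(e) NULL)
    if (is.null(fit_d) || !fit_d$converged) {
      return(list(loglik = NA_real_, converged = FALSE, iterations = it))
    }
    phi <- pmax(fit_d$fitted.values, eps_floor)
    ll <- gaussian_loglik(d, phi)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (floored) hv_log("debug", "dglm: squared residuals floored at machine epsilon")
  list(loglik = ll, converged = converged, iterations = it,
       coef_mean = fit_m$coefficients, coef_disp = fit_d$coefficients)
}

#' Double generalized linear model (dglm) test
#'
#' Parametric test that models the mean and the dispersion of the trait
#' jointly: a weighted least-squares fit of the mean (weights equal to the
#' reciprocal fitted dispersions) alternates with a gamma GLM with log link
#' for the dispersion (response = squared mean-model residuals, linear
#' predictor `lambda0 + lambda1 * x`, prior weights 1/2) until the fitted
#' Gaussian log-likelihood changes by less than 1e-8, or 50 iterations. The
#' test statistic is the likelihood ratio `2 * (l(lambda1 free) -
#' l(lambda1 = 0))` on the dispersion submodel, referred to a chi-square
#' distribution with 1 degree of freedom. Non-convergence of either fit is
#' reported via `converged = FALSE` with no p-value rather than an error.
#'
#' @inheritParams cls_test
#' @return a `het_test` result; `p_value` is `NULL` when `converged` is
#'   `FALSE`.
#' @export
dglm_test <- function(y, x) {
  n <- length(y)
  if (length(x) != n) stopf("invalid-argument: length(y) != length(x)")
  if (n < 6) stopf("invalid-argument: need at least 6 samples")
  if (stats::var(x) == 0) stopf("invalid-argument: covariate has zero variance")
  fit1 <- dglm_fit(y, x, dispersion_covariate = TRUE)
  fit0 <- dglm_fit(y, x, dispersion_covariate = FALSE)
  ok <- isTRUE(fit1$converged) && isTRUE(fit0$converged) &&
    is.finite(fit1$loglik) && is.finite(fit0$loglik)
  if (!ok) {
    hv_log("warning", "dglm did not converge (n = %d)", n)
    return(het_test_result("dglm", statistic = NA_real_, p_value = NULL,
                           df = 1, converged = FALSE, n = n))
  }
  lrt <- max(0, 2 * (fit1$loglik - fit0$loglik))
  het_test_result("dglm", statistic = lrt,
                  p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                  df = 1, converged = TRUE, n = n,
                  extra = list(lambda = fit1$coef_disp,
                               iterations = fit1$iterations))
}

#' Round genotype dosages to hard calls
#'
#' Explicit utility for converting continuous dosages in \[0, 2\] to the
#' most likely copy number \{0, 1, 2\}, as needed to apply group-based
#' variance tests to imputed genotypes in idealized simulations. Rounding
#' real dosage data this way discards imputation uncertainty and is
#' discouraged; the group-based tests therefore refuse continuous input
#' rather than rounding silently (see [run_test()]).
#'
#' @param x dosage vector.
#' @return integer vector over \{0, 1, 2\}.
#' @export
round_dosage <- function(x) {
  as.integer(pmin(2L, pmax(0L, round(x))))
}

#' Run any of the heteroskedasticity tests
#'
#' Uniform dispatcher over the six tests. The group-based tests (`levene`,
#' `brown_forsythe`, `bartlett`) require a categorical covariate
#' (whole-valued entries); continuous input raises an error instead of being
#' rounded silently — use [round_dosage()] explicitly if rounding is really
#' intended.
#'
#' @param method one of `"levene"`, `"brown_forsythe"`, `"bartlett"`,
#'   `"cls"`, `"dglm"`, `"bth"`.
#' @param y trait vector.
#' @param x covariate vector.
#' @param hyper hyperparameters forwarded to [bth_bayes_factor()] for
#'   `method = "bth"`.
#' @return a `het_test` result (for `"bth"` it carries `log10_bf` instead
#'   of a p-value).
#' @export
run_test <- function(method = c("levene", "brown_forsythe", "bartlett",
                                "cls", "dglm", "bth"),
                     y, x, hyper = bth_hyperparams()) {
  method <- match.arg(method)
  if (method %in% c("levene", "brown_forsythe", "bartlett") &&
      !is_wholenumber(x)) {
    stopf("invalid-argument: %s requires a categorical covariate; got continuous values (see round_dosage())",
          method)
  }
  switch(method,
    levene = levene_family_test(y, x, center = "mean"),
    brown_forsythe = levene_family_test(y, x, center = "median"),
    bartlett = bartlett_test(y, x),
    cls = cls_test(y, x),
    dglm = dglm_test(y, x),
    bth = {
      bf <- bth_bayes_factor(y, x, hyper)
      het_test_result("bth", statistic = NA_real_, p_value = NULL,
                      log10_bf = bf$log10_bf,
                      converged = bf$fit_alt$converged && bf$fit_null$converged,
                      n = bf$n,
                      extra = list(fit_alt = bf$fit_alt,
                                   fit_null = bf$fit_null))
    })
}

#' Write test results as a tab-delimited table
#'
#' @param results list of `het_test` objects.
#' @param path output file; the schema is `trait_id`, `covariate_id`,
#'   `method`, `statistic`, `p_value`, `log10_bf`, `converged`, `n`.
#' @param trait_ids,covariate_ids identifier vectors recycled against
#'   `results`.
#' @return the data.frame written, invisibly.
#' @export
write_test_results <- function(results, path, trait_ids = NULL,
                               covariate_ids = NULL) {
  nr <- length(results)
  df <- data.frame(
    trait_id = rep_len(trait_ids %||% sprintf("trait%05d", seq_len(nr)), nr),
    covariate_id = rep_len(covariate_ids %||% sprintf("cov%05d", seq_len(nr)), nr),
    method = vapply(results, `[[`, "", "method"),
    statistic = vapply(results, function(r) r$statistic %||% NA_real_, 1),
    p_value = vapply(results, function(r) r$p_value %||% NA_real_, 1),
    log10_bf = vapply(results, function(r) r$log10_bf %||% NA_real_, 1),
    converged = vapply(results, function(r) isTRUE(r$converged), TRUE),
    n = vapply(results, function(r) as.integer(r$n), 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
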