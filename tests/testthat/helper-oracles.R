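# Independent oracles used to validate the package's numerics.  They share
# no code path with the implementation: the Bayes-factor oracle marginalizes
# the intercept and the mean effect analytically through the 2x2 weighted
# least-squares system and integrates the remaining (log sigma2, log alpha)
# by nested adaptive quadrature; the other oracles are direct formula /
# enumeration evaluations.

# Gaussian linear model with design [1, x], flat prior on the intercept and
# N(0, 1/gamma) prior on the slope, marginalized analytically.  Computed
# through the QR factorization of the sqrt-weighted augmented design so that
# extreme log alpha values (weights spanning hundreds of e-folds) stay
# numerically stable.
oracle_joint_loglik <- function(y, x, ls, la, hyper) {
  n <- length(y)
  gam <- hyper$beta_prior_precision
  lw <- la * x - ls
  if (!all(is.finite(lw)) || max(lw) > 1200) return(-Inf)
  sw <- exp(lw / 2)
  Xa <- rbind(cbind(sw, sw * x), c(0, sqrt(gam)))
  ya <- c(sw * y, 0)
  qr_a <- qr(Xa)
  if (qr_a$rank < 2) return(-Inf)
  rss <- sum(qr.resid(qr_a, ya)^2)
  ldet_p <- 2 * sum(log(abs(diag(qr.R(qr_a)))))
  val <- -(n / 2) * log(2 * pi) + sum(lw) / 2 + log(gam) / 2 +
    log(2 * pi) / 2 - ldet_p / 2 - rss / 2
  if (!is.finite(val)) -Inf else val
}

# posterior kernel over (log sigma2, log alpha) WITHOUT the Cauchy factor
# (the la integral below absorbs the Cauchy prior by substitution)
oracle_posterior_kernel <- function(y, x, ls, la, hyper) {
  oracle_joint_loglik(y, x, ls, la, hyper) +
    (hyper$theta1 * log(hyper$theta2) - lgamma(hyper$theta1) -
       (hyper$theta1 + 1) * ls - hyper$theta2 / exp(ls)) + ls
}

oracle_log_marginal <- function(y, x, hyper = bth_hyperparams(),
                                alpha_free = TRUE) {
  ols <- stats::lm.fit(cbind(1, x), y)
  lsc <- log(max(sum(ols$residuals^2) / max(1, length(y) - 2), 1e-8))
  gmax <- oracle_posterior_kernel(y, x, lsc, 0, hyper)
  inner_ls <- function(la) {
    f <- function(lsv) vapply(lsv, function(ls)
      exp(oracle_posterior_kernel(y, x, ls, la, hyper) - gmax), 1)
    stats::integrate(f, lsc - 12, lsc + 12, rel.tol = 1e-8)$value
  }
  val <- if (alpha_free) {
    # substitute la = x0 + nu * tan(u): the Cauchy prior density becomes the
    # flat measure du / pi, so its heavy tails are integrated exactly
    fu <- function(uv) vapply(uv, function(u)
      inner_ls(hyper$x0 + hyper$nu * tan(u)) / pi, 1)
    stats::integrate(fu, -pi / 2 + 1e-10, pi / 2 - 1e-10,
                     rel.tol = 1e-7)$value
  } else {
    inner_ls(0)
  }
  log(val) + gmax
}

oracle_log10_bf <- function(y, x, hyper = bth_hyperparams()) {
  (oracle_log_marginal(y, x, hyper, TRUE) -
     oracle_log_marginal(y, x, hyper, FALSE)) / log(10)
}

# Direct evaluation of the Levene-family statistic from its definition.
oracle_levene_w <- function(y, x, center = "mean") {
  groups <- split(y, x)
  k <- length(groups)
  n <- length(y)
  cf <- if (center == "mean") mean else stats::median
  z <- lapply(groups, function(v) abs(v - cf(v)))
  zbar_t <- vapply(z, mean, 1)
  n_t <- lengths(z)
  zbar <- mean(unlist(z))
  num <- sum(n_t * (zbar_t - zbar)^2)
  den <- sum(unlist(lapply(seq_len(k), function(t) (z[[t]] - zbar_t[t])^2)))
  (n - k) * num / ((k - 1) * den)
}

# Textbook Bartlett chi-square statistic.
oracle_bartlett_stat <- function(y, x) {
  groups <- split(y, x)
  k <- length(groups)
  n_t <- lengths(groups)
  n <- sum(n_t)
  s2 <- vapply(groups, stats::var, 1)
  sp2 <- sum((n_t - 1) * s2) / (n - k)
  num <- (n - k) * log(sp2) - sum((n_t - 1) * log(s2))
  cc <- 1 + (sum(1 / (n_t - 1)) - 1 / (n - k)) / (3 * (k - 1))
  num / cc
}

# Brute-force Spearman rank correlation from order statistics.
oracle_spearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Brute-force precision-recall AUC by enumerating every distinct threshold.
oracle_pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  recall <- precision <- numeric(length(ths))
  for (i in seq_along(ths)) {
    sel <- scores >= ths[i]
    recall[i] <- sum(labels[sel]) / sum(labels)
    precision[i] <- sum(labels[sel]) / sum(sel)
  }
  rr <- c(0, recall)
  pp <- c(precision[1], precision)
  sum(diff(rr) * (pp[-1] + pp[-length(pp)]) / 2)
}

# Brute-force one-sided two-sample KS statistic D+ over a dense grid.
oracle_ks_dplus <- function(q, r) {
  grid <- sort(unique(c(q, r)))
  max(vapply(grid, function(t) mean(q <= t) - mean(r <= t), 1))
}

# Small helper: an ideal-model dataset for a given parameter row.
make_ideal_dataset <- function(n, maf, beta, log_alpha, beta0 = 0, seed = 1) {
  cfg <- sim_config(n = n, pi_maf = maf, beta0 = beta0, beta = beta,
                    log_alpha = log_alpha)
  simulate_dataset(cfg, seed = seed)
}
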