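# Expression preprocessing for variance-effect testing: log transform,
# principal-component confounder control, residualization and empirical
# quantile normalization.

top_pcs <- function(m, k) {
  # sample-level principal components of a (features x samples) matrix via
  # singular value decomposition of the column-centred transpose
  if (k == 0) return(NULL)
  a <- scale(t(m), center = TRUE, scale = FALSE)
  sv <- svd(a, nu = min(k, nrow(a)), nv = 0)
  sv$u[, seq_len(min(k, ncol(sv$u))), drop = FALSE]
}

residualize_rows <- function(m, design) {
  # per feature: least-squares residuals on the design, mean-centred;
  # collinear columns are dropped with a warning
  X <- cbind(1, design)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warnf("rank-deficient design: dropping %d collinear column(s)",
          ncol(X) - qr_x$rank)
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  res <- t(stats::lm.fit(X, t(m))$residuals)
  res - rowMeans(res)
}

#' Preprocess an expression matrix for variance-effect testing
#'
#' Pipeline, in order: (1) elementwise log2 of the expression values (which
#' must be strictly positive); (2) computation of the top `n_genotype_pcs`
#' sample-level principal components of the genotype matrix by singular
#' value decomposition, to control latent population structure; (3) per
#' gene, least-squares residualization on the known covariates plus the
#' genotype PCs, mean-centring the residuals; (4) computation of the top
#' `n_expression_pcs` PCs of the residual matrix and a second
#' residualization to control unknown confounders.
#'
#' @param traits features-by-samples expression matrix, strictly positive.
#' @param covariates optional samples-by-covariates numeric matrix of known
#'   covariates (age, sex, batch, ...).
#' @param genotypes optional variants-by-samples genotype matrix used for
#'   the population-structure PCs.
#' @param n_genotype_pcs number of genotype PCs (default 2).
#' @param n_expression_pcs number of expression PCs (default 2).
#' @return the processed matrix (same shape as `traits`).
#' @seealso [quantile_normalize()] for the final normalization step.
#' @export
preprocess_expression <- function(traits, covariates = NULL, genotypes = NULL,
                                  n_genotype_pcs = 2L, n_expression_pcs = 2L) {
  if (any(traits <= 0)) {
    stopf("invalid-argument: log2 step requires strictly positive trait values")
  }
  m <- log2(traits)
  geno_pcs <- if (!is.null(genotypes) && n_genotype_pcs > 0) {
    top_pcs(genotypes, n_genotype_pcs)
  }
  design <- cbind(covariates, geno_pcs)
  m <- if (is.null(design)) m - rowMeans(m) else residualize_rows(m, design)
  if (n_expression_pcs > 0) {
    expr_pcs <- top_pcs(m, n_expression_pcs)
    m <- residualize_rows(m, expr_pcs)
  }
  m
}

#' Empirical quantile normalization to standard-normal quantiles
#'
#' Replaces each feature row by the standard-normal quantiles of its ranks,
#' `qnorm((rank - 0.5) / n)` with average ranks for ties, so that every
#' (tie-free) feature has exactly the same value multiset and a marginal
#' distribution matching the standard normal. Constant features are mapped
#' to all zeros with a warning.
#'
#' @param traits features-by-samples numeric matrix without missing values.
#' @return the normalized matrix.
#' @export
quantile_normalize <- function(traits) {
  if (anyNA(traits)) stopf("invalid-argument: missing values not supported")
  n <- ncol(traits)
  out <- t(apply(traits, 1, function(v) {
    if (diff(range(v)) == 0) {
      warnf("constant feature mapped to all zeros")
      return(rep(0, n))
    }
    stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
  }))
  dimnames(out) <- dimnames(traits)
  out
}
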