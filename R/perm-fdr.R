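# Mean-effect-preserving permutation nulls and permutation-based FDR
# calibration.

#' Mean-effect-preserving permutation of a trait
#'
#' Builds a permutation null that keeps any mean effect of the covariate but
#' destroys variance effects: fit `y = beta0 + beta * x` by least squares,
#' permute the residuals uniformly at random, and add them back to the
#' fitted values. Each candidate permutation is screened by a two-sided
#' slope t-test of the permuted residuals against `x`; permutations with
#' p < 0.10 are redrawn (at most `max_redraws` times, after which the last
#' draw is accepted with a warning log), so the emitted null never carries a
#' detectable residual mean effect.
#'
#' The least-squares fit plays the role of the generalized least squares fit
#' in the original formulation; no residual covariance structure is modelled,
#' so the two coincide.
#'
#' @param y trait vector.
#' @param x covariate vector, non-constant.
#' @param seed optional integer seed.
#' @param accept_p acceptance threshold for the slope-test p-value
#'   (default 0.10).
#' @param max_redraws maximum number of redraws (default 100).
#' @return the permuted trait vector, with attributes `slope_p` (the
#'   accepted slope-test p-value), `redraws` and `forced` (`TRUE` when the
#'   redraw budget was exhausted).
#' @export
mean_preserving_permutation <- function(y, x, seed = NULL, accept_p = 0.10,
                                        max_redraws = 100L) {
  n <- length(y)
  if (length(x) != n) stopf("invalid-argument: length(y) != length(x)")
  if (stats::var(x) == 0) stopf("invalid-argument: covariate has zero variance")
  fit <- stats::lm.fit(cbind(1, x), y)
  fitted <- fit$fitted.values
  r <- fit$residuals
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope_p <- function(res) {
    b <- sum(xc * res) / sxx
    e <- res - mean(res) - b * xc
    s2 <- sum(e^2) / (n - 2)
    if (s2 <= 0) return(1)
    tt <- b / sqrt(s2 / sxx)
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  with_seed(seed, {
    redraws <- 0L
    repeat {
      perm <- sample.int(n)
      p <- slope_p(r[perm])
      if (p >= accept_p || redraws >= max_redraws) break
      redraws <- redraws + 1L
    }
    forced <- p < accept_p
    if (forced) {
      hv_log("warning",
             "permutation accepted after %d redraws with slope p = %.3g < %.2g",
             redraws, p, accept_p)
    }
    structure(fitted + r[perm], slope_p = p, redraws = redraws,
              forced = forced)
  })
}

#' Permutation-based FDR estimate at a threshold
#'
#' Estimates the false discovery rate at score threshold `t` as the ratio of
#' permutation-null exceedances to real exceedances,
#' `#\{perm > t\} / #\{real > t\}`, with the convention that the estimate is
#' 0 when there are no discoveries. For signed scores (log Bayes factors)
#' set `absolute = TRUE` to compare `|score| > t`.
#'
#' @param real_scores scores of the real tests (larger = more significant;
#'   use `-log10(p)` for p-value based methods).
#' @param perm_scores scores of the matched permutation-null tests.
#' @param threshold score threshold(s); vectorized.
#' @param absolute compare absolute values (for signed Bayes factors).
#' @return numeric FDR estimate(s), >= 0 (may exceed 1 when the permutation
#'   tail is heavier than the real tail).
#' @export
#' @examples
#' estimate_fdr(c(3, 2, 1), c(1.5, 0.5, 0.2), 1.4)  # 0.5
estimate_fdr <- function(real_scores, perm_scores, threshold,
                         absolute = FALSE) {
  if (length(real_scores) == 0 || length(perm_scores) == 0) {
    stopf("invalid-argument: score collections must be non-empty")
  }
  if (absolute) {
    real_scores <- abs(real_scores)
    perm_scores <- abs(perm_scores)
  }
  vapply(threshold, function(t) {
    n_real <- sum(real_scores > t)
    if (n_real == 0) return(0)
    sum(perm_scores > t) / n_real
  }, 1)
}

#' FDR estimates over a threshold grid
#'
#' @inheritParams estimate_fdr
#' @param thresholds candidate thresholds; defaults to all observed score
#'   values (real and permutation pooled), ascending.
#' @return an object of class `fdr_curve`: list with `thresholds`
#'   (ascending), `fdr_at`, `n_real` and `n_perm`.
#' @export
fdr_curve <- function(real_scores, perm_scores, thresholds = NULL,
                      absolute = FALSE) {
  if (absolute) {
    real_scores <- abs(real_scores)
    perm_scores <- abs(perm_scores)
  }
  thresholds <- sort(unique(thresholds %||% c(real_scores, perm_scores)))
  structure(
    list(thresholds = thresholds,
         fdr_at = estimate_fdr(real_scores, perm_scores, thresholds),
         n_real = length(real_scores), n_perm = length(perm_scores)),
    class = "fdr_curve")
}

#' Calibrate a score threshold at a nominal FDR level
#'
#' Scans the observed score values (real and permutation pooled, ascending)
#' and returns the smallest threshold whose estimated FDR is at or below the
#' nominal level, together with the discoveries exceeding it (descending
#' score order). When no threshold attains the level, the calibrated
#' threshold is `+Inf` with zero discoveries — not an error.
#'
#' @inheritParams estimate_fdr
#' @param level nominal FDR in (0, 1), e.g. 0.05.
#' @param ids optional identifiers for the real scores (used to label
#'   discoveries).
#' @return an object of class `calibrated_threshold`: list with `level`,
#'   `d_fdr`, `fdr_at_d`, `discoveries` (data.frame with `id` and `score`,
#'   descending) and `n_discoveries`.
#' @export
calibrate_threshold <- function(real_scores, perm_scores, level,
                                absolute = FALSE, ids = NULL) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stopf("invalid-argument: level must lie in (0, 1)")
  }
  ids <- ids %||% seq_along(real_scores)
  cmp_real <- if (absolute) abs(real_scores) else real_scores
  cmp_perm <- if (absolute) abs(perm_scores) else perm_scores
  cand <- sort(unique(c(cmp_real, cmp_perm)))
  fdr <- estimate_fdr(cmp_real, cmp_perm, cand)
  ok <- which(fdr <= level & vapply(cand, function(t) sum(cmp_real > t) > 0, TRUE))
  if (length(ok) == 0) {
    d <- Inf
    disc <- data.frame(id = ids[0], score = numeric(0))
  } else {
    d <- cand[min(ok)]
    sel <- which(cmp_real > d)
    ord <- sel[order(cmp_real[sel], decreasing = TRUE)]
    disc <- data.frame(id = ids[ord], score = real_scores[ord])
  }
  structure(
    list(level = level, d_fdr = d,
         fdr_at_d = if (is.finite(d)) estimate_fdr(cmp_real, cmp_perm, d) else 0,
         discoveries = disc, n_discoveries = nrow(disc)),
    class = "calibrated_threshold")
}

#' @export
print.calibrated_threshold <- function(x, ...) {
  cat(sprintf("<calibrated_threshold> level=%.3g d_fdr=%.4g discoveries=%d\n",
              x$level, x$d_fdr, x$n_discoveries))
  invisible(x)
}

#' MAF-stratified FDR calibration
#'
#' Applies [calibrate_threshold()] independently within bins of minor allele
#' frequency, so that score inflation confined to (say) low-MAF covariates
#' does not leak discoveries across the frequency spectrum. Empty bins are
#' skipped with a warning log.
#'
#' @param scores data.frame with columns `score`, `maf`, `is_perm`
#'   (logical) and optionally `id`.
#' @param level nominal FDR in (0, 1).
#' @param bins ascending bin edges partitioning (0, 0.5\]; default
#'   `c(0.05, 0.1, 0.2, 0.3, 0.5)` giving bins \[0.05,0.1), \[0.1,0.2),
#'   \[0.2,0.3), \[0.3,0.5\].
#' @param absolute compare absolute scores (signed Bayes factors).
#' @return list with one `calibrated_threshold` per non-empty bin (named by
#'   bin) and `discoveries`, the union of per-bin discoveries with bin
#'   provenance.
#' @export
maf_stratified_fdr <- function(scores, level, bins = c(0.05, 0.1, 0.2, 0.3, 0.5),
                               absolute = FALSE) {
  stopifnot(is.data.frame(scores),
            all(c("score", "maf", "is_perm") %in% names(scores)))
  if (anyNA(scores$maf)) stopf("invalid-argument: every covariate needs a MAF annotation")
  scores$id <- scores$id %||% seq_len(nrow(scores))
  cut_bin <- cut(scores$maf, breaks = bins, right = FALSE,
                 include.lowest = TRUE)
  out <- list()
  disc <- NULL
  for (b in levels(cut_bin)) {
    idx <- which(cut_bin == b)
    real <- scores[idx, ][!scores$is_perm[idx], ]
    perm <- scores[idx, ][scores$is_perm[idx], ]
    if (nrow(real) == 0 || nrow(perm) == 0) {
      hv_log("warning", "MAF bin %s is empty; skipped", b)
      next
    }
    ct <- calibrate_threshold(real$score, perm$score, level,
                              absolute = absolute, ids = real$id)
    out[[b]] <- ct
    if (ct$n_discoveries > 0) {
      d <- ct$discoveries
      d$maf_bin <- b
      disc <- rbind(disc, d)
    }
  }
  out$discoveries <- disc %||% data.frame(id = integer(0), score = numeric(0),
                                          maf_bin = character(0))
  out
}
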