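# Precision-recall evaluation and the simulation benchmarking harness.

#' Precision-recall curve
#'
#' Standard precision-recall curve over descending score thresholds with
#' tied scores grouped at a single threshold (no arbitrary intra-tie
#' ordering). The curve is anchored at recall 0 with the precision of the
#' first threshold group; `auc` is trapezoidal integration of precision over
#' recall, and `average_precision` is the mean of the precision at each
#' newly recalled positive.
#'
#' @param scores numeric scores, larger = more evidence.
#' @param labels 0/1 (or logical) labels, 1 = true positive class.
#' @return an object of class `pr_curve`: list with `recall`, `precision`
#'   (per threshold group, recall ascending), `auc`, `average_precision`,
#'   `n_pos`, `n_neg`.
#' @export
#' @examples
#' pr <- precision_recall(c(3, 2.5, 2, 1), c(1, 1, 0, 0))
#' pr$auc  # 1: perfectly separated
precision_recall <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stopf("invalid-argument: scores and labels differ in length")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stopf("invalid-argument: need at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group ties: last index of each distinct score value
  grp_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(1L - l)[grp_end]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  # trapezoid over recall, anchored at (0, precision[1])
  rr <- c(0, recall)
  pp <- c(precision[1], precision)
  auc <- sum(diff(rr) * (pp[-1] + pp[-length(pp)]) / 2)
  ap <- sum(diff(c(0, recall)) * precision)
  structure(
    list(recall = recall, precision = precision, auc = auc,
         average_precision = ap, n_pos = n_pos, n_neg = n_neg),
    class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> AUC = %.4f, AP = %.4f (%d+/%d-)\n",
              x$auc, x$average_precision, x$n_pos, x$n_neg))
  invisible(x)
}

#' Score a dataset with one method
#'
#' Converts a test result into the unified score orientation "larger = more
#' evidence of heteroskedasticity": the log10 Bayes factor for `bth`,
#' `-log10(p)` for the p-value based methods. Non-converged dglm fits score
#' 0 (no evidence) rather than being dropped, so every method sees the same
#' label set.
#'
#' @param dataset a `sim_dataset` (or any list with `x` and `y`).
#' @param method method name accepted by [run_test()].
#' @param hyper hyperparameters for `bth`.
#' @return list with `score` and `converged`.
#' @export
score_dataset <- function(dataset, method, hyper = bth_hyperparams()) {
  res <- run_test(method, dataset$y, dataset$x, hyper = hyper)
  if (!is.null(res$log10_bf)) {
    list(score = res$log10_bf, converged = isTRUE(res$converged))
  } else if (!isTRUE(res$converged) || is.null(res$p_value)) {
    list(score = 0, converged = FALSE)
  } else {
    list(score = -log10(max(res$p_value, .Machine$double.xmin)),
         converged = TRUE)
  }
}

#' Run the simulation benchmark
#'
#' For each configuration, `reps` real datasets plus `reps` matched
#' mean-effect-preserving permutation nulls are generated (see
#' [generate_benchmark_suite()]) and scored by every method; a
#' precision-recall curve of real-versus-permutation discrimination is
#' computed per method. Methods incompatible with a configuration's
#' covariate kind (the group-based tests on continuous dosages) cause that
#' (config, method) cell to be skipped with a warning.
#'
#' @param configs a [sim_config()] or list of them.
#' @param methods character vector of method names (see [run_test()]).
#' @param reps replicates per configuration.
#' @param seed master seed; the suite and all scoring are deterministic.
#' @param hyper hyperparameters for `bth`.
#' @return list with `table` (data.frame: config fields, method, auc,
#'   average_precision, n_converged), `scores` (long data.frame of all
#'   scores with labels) and `curves` (list of `pr_curve` keyed by
#'   "config/method").
#' @export
run_benchmark <- function(configs, methods = c("levene", "brown_forsythe",
                                               "cls", "dglm", "bth"),
                          reps = 100L, seed = 1L,
                          hyper = bth_hyperparams()) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  tab <- NULL
  all_scores <- NULL
  curves <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    suite <- generate_benchmark_suite(cfg, reps, seed = seed_stream(seed, ci))
    labels <- as.integer(!vapply(suite, `[[`, TRUE, "is_permutation_null"))
    categorical <- is_wholenumber(suite[[1]]$x) &&
      all(vapply(suite, function(d) is_wholenumber(d$x), TRUE))
    for (m in methods) {
      if (m %in% c("levene", "brown_forsythe", "bartlett") && !categorical) {
        warnf("method %s skipped for config %d: continuous covariate", m, ci)
        next
      }
      sc <- lapply(suite, score_dataset, method = m, hyper = hyper)
      scores <- vapply(sc, `[[`, 1, "score")
      conv <- vapply(sc, `[[`, TRUE, "converged")
      pr <- precision_recall(scores, labels)
      key <- sprintf("config%d/%s", ci, m)
      curves[[key]] <- pr
      tab <- rbind(tab, data.frame(
        config = ci, n = cfg$n, pi_maf = cfg$pi_maf, beta = cfg$beta,
        log_alpha = cfg$log_alpha, family = cfg$family, method = m,
        auc = pr$auc, average_precision = pr$average_precision,
        n_converged = sum(conv)))
      all_scores <- rbind(all_scores, data.frame(
        config = ci, dataset = seq_along(suite), method = m,
        score = scores, label = labels, converged = conv))
    }
  }
  list(table = tab, scores = all_scores, curves = curves)
}

#' Compare two methods on a benchmark
#'
#' Reports the AUC and average-precision differences between two methods on
#' one benchmark configuration, with bootstrap percentile intervals obtained
#' by resampling datasets (both methods re-evaluated on the same resample).
#'
#' @param benchmark result of [run_benchmark()].
#' @param method_a,method_b method names present in the benchmark.
#' @param config configuration index (default 1).
#' @param n_boot bootstrap draws (default 1000).
#' @param level interval coverage (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list with `auc_diff`, `ap_diff`, `auc_ci`, `ap_ci`.
#' @export
compare_methods <- function(benchmark, method_a, method_b, config = 1L,
                            n_boot = 1000L, level = 0.95, seed = 1L) {
  sc <- benchmark$scores
  sa <- sc[sc$config == config & sc$method == method_a, ]
  sb <- sc[sc$config == config & sc$method == method_b, ]
  if (nrow(sa) == 0 || nrow(sb) == 0) {
    stopf("invalid-argument: both methods must be present for config %d", config)
  }
  sa <- sa[order(sa$dataset), ]
  sb <- sb[order(sb$dataset), ]
  pr_a <- precision_recall(sa$score, sa$label)
  pr_b <- precision_recall(sb$score, sb$label)
  out <- list(auc_diff = pr_a$auc - pr_b$auc,
              ap_diff = pr_a$average_precision - pr_b$average_precision)
  if (identical(method_a, method_b)) {
    out$auc_ci <- c(0, 0)
    out$ap_ci <- c(0, 0)
    return(out)
  }
  n <- nrow(sa)
  with_seed(seed, {
    draws <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(sa$label[idx])) < 2) {
        draws[b, ] <- c(NA, NA)
        next
      }
      pa <- precision_recall(sa$score[idx], sa$label[idx])
      pb <- precision_recall(sb$score[idx], sb$label[idx])
      draws[b, ] <- c(pa$auc - pb$auc,
                      pa$average_precision - pb$average_precision)
    }
    alpha <- (1 - level) / 2
    out$auc_ci <- unname(stats::quantile(draws[, 1], c(alpha, 1 - alpha),
                                         na.rm = TRUE))
    out$ap_ci <- unname(stats::quantile(draws[, 2], c(alpha, 1 - alpha),
                                        na.rm = TRUE))
  })
  out
}

#' Write a benchmark report as TSV
#'
#' @param benchmark result of [run_benchmark()].
#' @param path output file.
#' @return the table written, invisibly.
#' @export
write_benchmark_report <- function(benchmark, path) {
  utils::write.table(benchmark$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(benchmark$table)
}
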