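# Tab-delimited I/O for trait matrices, covariate tables and cis pairing.
# Conventions: first column = feature/covariate identifiers, header row =
# sample identifiers, UTF-8, "NA" or empty cells mean missing.  All genomic
# coordinates are 1-based inclusive.

read_matrix_tsv <- function(path, what) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1]])
  samples <- colnames(df)[-1]
  if (anyDuplicated(ids)) {
    stopf("format error in %s: duplicate %s identifier '%s'", path, what,
          ids[duplicated(ids)][1])
  }
  if (anyDuplicated(samples)) {
    stopf("format error in %s: duplicate sample identifier '%s'", path,
          samples[duplicated(samples)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))) &
                   !is.na(as.matrix(df[, -1, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stopf("format error in %s: non-numeric cell at row '%s', column '%s'",
            path, ids[bad[1, 1]], samples[bad[1, 2]])
    }
    m <- apply(df[, -1, drop = FALSE], 2, as.numeric)
  }
  rownames(m) <- ids
  hv_log("info", "read %s: %d rows x %d samples", path, nrow(m), ncol(m))
  m
}

#' Read / write a trait matrix
#'
#' Tab-delimited matrix of trait values, rows = features, columns = samples,
#' first column holding feature identifiers. Duplicate identifiers or
#' non-numeric cells raise a format error naming the offender.
#'
#' @param path file path.
#' @return `read_trait_matrix()` returns a numeric matrix with feature row
#'   names and sample column names.
#' @export
read_trait_matrix <- function(path) {
  read_matrix_tsv(path, "feature")
}

#' @rdname read_trait_matrix
#' @param m numeric matrix with row and column names.
#' @param id_column name of the identifier column written first.
#' @export
write_trait_matrix <- function(m, path, id_column = "id") {
  # %.17g keeps doubles exact under write-then-read round trips
  fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

infer_covariate_kind <- function(v) {
  v <- v[!is.na(v)]
  if (all(v %in% c(0, 1))) "binary"
  else if (is_wholenumber(v) && all(v %in% c(0, 1, 2))) "discrete"
  else if (all(v >= 0 & v <= 2)) "dosage"
  else "continuous"
}

#' Read a covariate table
#'
#' Same layout as [read_trait_matrix()] (rows = covariates, columns =
#' samples). The kind of each covariate is inferred from its values —
#' `binary` (subset of \{0,1\}), `discrete` (\{0,1,2\}), `dosage`
#' (\[0,2\]) or `continuous` — and the minor allele frequency is computed
#' for genotype-like kinds as `min(m, 1-m)` with `m = mean(value)/2`
#' (`mean(value)` for binary).
#'
#' @param path file path.
#' @return an object of class `covariate_table`: list with `values`
#'   (matrix), `kind` (named character) and `maf` (named numeric, `NA` for
#'   continuous covariates).
#' @export
read_covariate_table <- function(path) {
  m <- read_matrix_tsv(path, "covariate")
  covariate_table(m)
}

#' @rdname read_covariate_table
#' @param values covariate-by-sample numeric matrix.
#' @export
covariate_table <- function(values) {
  kind <- apply(values, 1, infer_covariate_kind)
  maf <- vapply(seq_len(nrow(values)), function(i) {
    v <- values[i, ]
    v <- v[!is.na(v)]
    switch(kind[i],
      binary = {
        m <- mean(v)
        min(m, 1 - m)
      },
      discrete = ,
      dosage = {
        m <- mean(v) / 2
        min(m, 1 - m)
      },
      NA_real_)
  }, 1)
  names(maf) <- rownames(values)
  structure(list(values = values, kind = kind, maf = maf),
            class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(sprintf("<covariate_table> %d covariates x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$kind)), table(x$kind)),
                    collapse = ", ")))
  invisible(x)
}

#' Filter covariates by minor allele frequency
#'
#' Removes covariates whose MAF (computed as `min(m, 1-m)` with
#' `m = mean/2` for genotype dosages) falls below `min_maf`; continuous
#' covariates without a MAF are kept.
#'
#' @param covariates a [covariate_table()].
#' @param min_maf minimum MAF retained (e.g. 0.05).
#' @return the filtered `covariate_table`.
#' @export
filter_maf <- function(covariates, min_maf) {
  stopifnot(inherits(covariates, "covariate_table"))
  drop <- !is.na(covariates$maf) & covariates$maf < min_maf
  hv_log("info", "filter_maf: removed %d of %d covariates below MAF %.3g",
         sum(drop), length(drop), min_maf)
  covariate_table(covariates$values[!drop, , drop = FALSE])
}

#' Enumerate cis (feature, variant) pairs
#'
#' Pairs every feature with every variant on the same chromosome whose
#' position lies within `window` bases of the feature interval
#' `[start, end]` (1-based inclusive; distance 0 inside the interval,
#' otherwise distance to the nearest interval edge; the boundary
#' `distance == window` is included).
#'
#' @param features data.frame with columns `id`, `chrom`, `start`, `end`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`.
#' @param window window size in bases.
#' @return data.frame with `trait_id`, `covariate_id`, `distance`.
#' @export
make_cis_pairs <- function(features, variants, window) {
  need_f <- c("id", "chrom", "start", "end")
  need_v <- c("id", "chrom", "pos")
  if (!all(need_f %in% names(features)) || anyNA(features[need_f])) {
    stopf("invalid-argument: features need complete columns %s",
          paste(need_f, collapse = ", "))
  }
  if (!all(need_v %in% names(variants)) || anyNA(variants[need_v])) {
    stopf("invalid-argument: variants need complete columns %s",
          paste(need_v, collapse = ", "))
  }
  out <- NULL
  for (chr in intersect(unique(features$chrom), unique(variants$chrom))) {
    f <- features[features$chrom == chr, ]
    v <- variants[variants$chrom == chr, ]
    for (i in seq_len(nrow(f))) {
      d <- ifelse(v$pos < f$start[i], f$start[i] - v$pos,
                  ifelse(v$pos > f$end[i], v$pos - f$end[i], 0))
      keep <- d <= window
      if (any(keep)) {
        out <- rbind(out, data.frame(trait_id = f$id[i],
                                     covariate_id = v$id[keep],
                                     distance = d[keep]))
      }
    }
  }
  out %||% data.frame(trait_id = character(0), covariate_id = character(0),
                      distance = numeric(0))
}
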