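# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_wholenumber <- function(x, tol = 1e-8) {
  all(is.finite(x)) && all(abs(x - round(x)) <= tol)
}

#' Package logging
#'
#' Structured one-line log messages. Verbosity is controlled by
#' `options(hetvar.verbose = )`, one of `"debug"`, `"info"`, `"warning"`
#' (default) or `"none"`.
#'
#' @param level message level, one of `"debug"`, `"info"`, `"warning"`.
#' @param fmt,... `sprintf()` format and arguments.
#' @return invisibly, the formatted message.
#' @keywords internal
hv_log <- function(level = "info", fmt = "", ...) {
  ranks <- c(debug = 1L, info = 2L, warning = 3L, none = 4L)
  opt <- getOption("hetvar.verbose", "warning")
  msg <- sprintf(fmt, ...)
  if (ranks[[level]] >= ranks[[opt]]) {
    message(sprintf("[hetvar:%s] %s", level, msg))
  }
  invisible(msg)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.  A NULL seed evaluates in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-stream seed
#'
#' Datasets in a simulation suite each receive their own seed derived from a
#' single master seed plus a counter, so that suites are reproducible
#' regardless of the order in which datasets are generated.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer index of the sub-stream.
#' @return an integer seed below 2^31.
#' @export
seed_stream <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(counter), all(counter >= 0))
  s <- (abs(as.double(seed)) %% 2146319)
  as.integer(((s + 1) * 48271 + as.double(counter) * 7919) %% 2147483629)
}
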