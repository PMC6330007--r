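#' Prescriptive trait transformations
#'
#' `transform_spec()` builds a transformation recommendation and
#' `apply_transformation()` applies it. Two non-trivial transformations are
#' supported: a natural-log transform for traits that look log-Gaussian
#' (requires strictly positive values), and a mean-centred square-root
#' transform for gamma-looking traits (requires non-negative values; the
#' mean of the square roots is subtracted so the output mean is exactly 0,
#' and the subtracted offset is recorded in the spec).
#'
#' These transformations exist to remove *spurious* variance signal: in
#' log-Gaussian or gamma traits the variance is a function of the mean, so a
#' pure mean effect masquerades as heteroskedasticity; after the matching
#' transformation such weak-null traits stop triggering the variance tests.
#'
#' @param kind one of `"none"`, `"log"`, `"mean_centered_sqrt"`.
#' @param offset fitted offset (the subtracted mean for
#'   `mean_centered_sqrt`; filled in by `apply_transformation()`).
#' @return `transform_spec()` returns an object of class `transform_spec`;
#'   `apply_transformation()` returns the transformed trait vector with the
#'   fitted spec attached as attribute `"spec"`.
#' @export
transform_spec <- function(kind = c("none", "log", "mean_centered_sqrt"),
                           offset = NA_real_) {
  kind <- match.arg(kind)
  structure(list(kind = kind, offset = offset), class = "transform_spec")
}

#' @rdname transform_spec
#' @param y trait vector.
#' @param spec a `transform_spec`.
#' @export
#' @examples
#' z <- rnorm(50)
#' all.equal(apply_transformation(exp(z), transform_spec("log")), z,
#'           check.attributes = FALSE)
apply_transformation <- function(y, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$kind,
    none = structure(y, spec = spec),
    log = {
      if (any(y <= 0)) stopf("invalid-argument: log transform requires strictly positive values")
      structure(log(y), spec = spec)
    },
    mean_centered_sqrt = {
      if (any(y < 0)) stopf("invalid-argument: square-root transform requires non-negative values")
      s <- sqrt(y)
      off <- mean(s)
      spec$offset <- off
      structure(s - off, spec = spec)
    })
}

#' Transformation recommended for a distribution class
#'
#' Maps a trait-distribution class label to the prescriptive
#' transformation: `log_gaussian` to the log transform, `gamma` to the
#' mean-centred square root, everything else to no transformation.
#'
#' @param label a class label (see [train_classifier()]).
#' @return a [transform_spec()].
#' @export
recommend_transformation <- function(label) {
  switch(as.character(label),
    log_gaussian = transform_spec("log"),
    gamma = transform_spec("mean_centered_sqrt"),
    transform_spec("none"))
}
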