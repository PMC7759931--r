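#' Per-feature transform specification
#'
#' Variance-stabilizing / linearizing transforms applied to features before
#' modelling: identity, `log(f)`, `log(a + f)` or `log(log(f) + a)`,
#' optionally followed by a z-score whose constants are stored at fit time
#' and reused at evaluation (training-set constants are never recomputed on
#' new data).
#'
#' @param kind one of `"identity"`, `"log"`, `"log_shift"`,
#'   `"loglog_shift"`.
#' @param shift the constant `a` for the shifted kinds.
#' @param zscore whether to z-score after transforming.
#' @param mean,sd stored standardization constants (filled by
#'   [apply_transform()] when `zscore = TRUE` and constants are absent).
#' @return object of class `transform_spec`.
#' @export
transform_spec <- function(kind = c("identity", "log", "log_shift",
                                    "loglog_shift"),
                           shift = 0, zscore = FALSE, mean = NA_real_,
                           sd = NA_real_) {
  kind <- match.arg(kind)
  structure(list(kind = kind, shift = shift, zscore = zscore,
                 mean = mean, sd = sd),
            class = "transform_spec")
}

#' Apply (and optionally fit) a transform
#'
#' Elementwise transform of a feature vector. A log of a non-positive
#' argument is an error naming the offending value (and feature, when
#' given). When `spec$zscore` is TRUE and the constants are unset they are
#' computed from `values` and returned in the updated spec, so the same
#' constants standardize future data.
#'
#' @param values numeric vector.
#' @param spec a [transform_spec()].
#' @param feature_name used in error messages.
#' @return list with `values` (transformed) and `spec` (with any fitted
#'   constants).
#' @export
apply_transform <- function(values, spec, feature_name = "feature") {
  stopifnot(inherits(spec, "transform_spec"))
  x <- switch(spec$kind,
    identity = values,
    log = {
      .check_pos(values, feature_name, "log(f)")
      log(values)
    },
    log_shift = {
      .check_pos(spec$shift + values, feature_name,
                 sprintf("log(%g + f)", spec$shift))
      log(spec$shift + values)
    },
    loglog_shift = {
      .check_pos(values, feature_name, "log(f)")
      arg <- log(values) + spec$shift
      .check_pos(arg, feature_name,
                 sprintf("log(log(f) + %g)", spec$shift))
      log(arg)
    })
  if (isTRUE(spec$zscore)) {
    if (is.na(spec$mean) || is.na(spec$sd)) {
      spec$mean <- mean(x, na.rm = TRUE)
      spec$sd <- sd(x)
      if (is.na(spec$sd) || spec$sd == 0)
        stop(sprintf("cannot z-score constant feature '%s'", feature_name),
             call. = FALSE)
    }
    x <- (x - spec$mean) / spec$sd
  }
  list(values = x, spec = spec)
}

.check_pos <- function(x, feature_name, what) {
  bad <- which(x <= 0)
  if (length(bad))
    stop(sprintf("%s undefined for feature '%s': value %g at position %d",
                 what, feature_name, x[bad[1]], bad[1]), call. = FALSE)
  invisible(TRUE)
}

#' Default transform registry
#'
#' Named list of [transform_spec()]s keyed by feature name, with an
#' `.default` entry for unlisted features. Lesion volume is modelled on the
#' log scale; the radiomics-signature features carry the transforms used in
#' its definition (`log` for GLNUz and Coarseness, `log(log(f) + 9)` for
#' LGRE, identity for Correlation and StdDev); everything else defaults to
#' identity (transform choice is configuration, not automated search).
#'
#' @return named list of transform specs.
#' @export
default_transform_registry <- function() {
  list(
    Volume = transform_spec("log"),
    GLNUz = transform_spec("log"),
    Coarseness = transform_spec("log"),
    LGRE = transform_spec("loglog_shift", shift = 9),
    .default = transform_spec("identity")
  )
}

# Look up the transform for a feature name.
.registry_spec <- function(registry, name) {
  if (!is.null(registry[[name]])) registry[[name]]
  else if (!is.null(registry$.default)) registry$.default
  else transform_spec("identity")
}
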