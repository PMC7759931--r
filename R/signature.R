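#' Pick the top-5 features from a volume-adjusted screen
#'
#' The five real features with the smallest likelihood-ratio-test p-values
#' in the volume-adjusted screen; spiked random predictors are excluded
#' even when their p is small. Ties are broken by feature name order.
#'
#' @param screen a `screen_result` computed with `adjust_volume = TRUE`.
#' @param k number of features (default 5).
#' @return character vector of feature names.
#' @export
pick_top5 <- function(screen, k = 5) {
  if (is.null(screen$lrt_p))
    stop("screen has no LRT p-values; run with adjust_volume = TRUE",
         call. = FALSE)
  real <- screen[!screen$is_random, , drop = FALSE]
  real <- real[real$feature != "Volume", , drop = FALSE]
  if (nrow(real) < k)
    stop(sprintf("need at least %d real features, have %d", k,
                 nrow(real)), call. = FALSE)
  real <- real[order(real$lrt_p, real$feature), , drop = FALSE]
  real$feature[seq_len(k)]
}

#' Build a radiomics signature model
#'
#' Constructs a PCA-based signature over named features: each feature is
#' transformed per its registry entry, z-scored with stored constants, and
#' the signature is the first principal axis of the standardized matrix
#' (PCA on the correlation scale), i.e. an affine function of the
#' transformed inputs. The loading sign is fixed so the signature
#' correlates positively with the training response (by convention
#' `|log(maf)|`; the sign pattern of a PCA axis is otherwise arbitrary).
#'
#' @param data data.frame holding the feature columns (training rows).
#' @param feature_names ordered names of the signature features.
#' @param response training response used only for the sign convention
#'   (e.g. `abs(log_maf)`); NULL keeps the raw eigenvector sign.
#' @param registry transform registry.
#' @param min_eigengap minimal gap between the first two eigenvalues; an
#'   ambiguous first axis is an error.
#' @return object of class `signature_model`: feature names, per-feature
#'   transform specs (with stored standardization constants), unit-norm
#'   loading vector, sign convention record, explained variance share.
#' @export
fit_pca_signature <- function(data, feature_names,
                              response = NULL,
                              registry = default_transform_registry(),
                              min_eigengap = 1e-8) {
  Z <- matrix(NA_real_, nrow(data), length(feature_names))
  specs <- vector("list", length(feature_names))
  names(specs) <- feature_names
  for (i in seq_along(feature_names)) {
    nm <- feature_names[i]
    if (is.null(data[[nm]]))
      stop(sprintf("feature '%s' not found", nm), call. = FALSE)
    sp <- .registry_spec(registry, nm)
    sp$zscore <- TRUE
    sp$mean <- NA_real_; sp$sd <- NA_real_
    tr <- apply_transform(data[[nm]], sp, nm)
    Z[, i] <- tr$values
    specs[[i]] <- tr$spec
  }
  ev <- eigen(stats::cov(Z), symmetric = TRUE)
  if (length(feature_names) > 1 &&
      (ev$values[1] - ev$values[2]) < min_eigengap)
    stop("first principal axis is ambiguous (eigengap below tolerance)",
         call. = FALSE)
  loadings <- ev$vectors[, 1]
  loadings <- loadings / sqrt(sum(loadings^2))
  sign_convention <- "eigenvector"
  if (!is.null(response)) {
    sc <- as.vector(Z %*% loadings)
    r <- suppressWarnings(cor(sc, response))
    if (is.finite(r) && r < 0) loadings <- -loadings
    sign_convention <- "positive correlation with training response"
  }
  names(loadings) <- feature_names
  structure(list(features = feature_names, transforms = specs,
                 loadings = loadings,
                 sign_convention = sign_convention,
                 var_explained = ev$values[1] / sum(ev$values)),
            class = "signature_model")
}

#' Construct a signature model from explicit constants
#'
#' Builds a `signature_model` directly from loading coefficients, transform
#' specs and standardization constants — e.g. to evaluate a published
#' signature on new data, or to freeze a fitted one.
#'
#' @param feature_names ordered feature names.
#' @param loadings numeric loading vector (same order).
#' @param transforms optional named list of [transform_spec()]s; default
#'   identity transforms with identity standardization (mean 0, sd 1) so
#'   inputs are taken as already standardized.
#' @return a `signature_model`.
#' @export
signature_model <- function(feature_names, loadings, transforms = NULL) {
  stopifnot(length(feature_names) == length(loadings))
  if (is.null(transforms)) {
    transforms <- lapply(feature_names, function(nm)
      transform_spec("identity", zscore = TRUE, mean = 0, sd = 1))
    names(transforms) <- feature_names
  }
  loadings <- as.numeric(loadings)
  names(loadings) <- feature_names
  structure(list(features = feature_names, transforms = transforms,
                 loadings = loadings, sign_convention = "as supplied",
                 var_explained = NA_real_),
            class = "signature_model")
}

#' Evaluate a radiomics signature
#'
#' `sum_i loading_i * z_i(transform_i(value_i))` with the stored transform
#' and standardization constants; an affine function of the transformed
#' inputs. Missing features are an error naming the first one missing.
#'
#' @param model a `signature_model`.
#' @param newdata data.frame (or named list/vector) with the feature
#'   columns.
#' @return numeric vector of signature values.
#' @export
evaluate_signature <- function(model, newdata) {
  stopifnot(inherits(model, "signature_model"))
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  out <- 0
  for (nm in model$features) {
    if (is.null(newdata[[nm]]))
      stop(sprintf("missing signature feature '%s'", nm), call. = FALSE)
    tr <- apply_transform(newdata[[nm]], model$transforms[[nm]], nm)
    out <- out + model$loadings[[nm]] * tr$values
  }
  as.numeric(out)
}

#' Serialize / restore a signature model as JSON
#' @param model a `signature_model`.
#' @param path JSON file path.
#' @return `write_signature_json` returns the path invisibly;
#'   `read_signature_json` returns the model.
#' @export
write_signature_json <- function(model, path) {
  obj <- list(features = model$features,
              loadings = as.numeric(model$loadings),
              sign_convention = model$sign_convention,
              var_explained = model$var_explained,
              transforms = lapply(model$transforms, function(sp)
                list(kind = sp$kind, shift = sp$shift,
                     zscore = sp$zscore, mean = sp$mean, sd = sp$sd)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  transforms <- lapply(seq_along(obj$features), function(i) {
    tr <- if (is.data.frame(obj$transforms)) obj$transforms[i, ]
          else obj$transforms[[i]]
    transform_spec(tr$kind, shift = tr$shift, zscore = tr$zscore,
                   mean = tr$mean, sd = tr$sd)
  })
  names(transforms) <- obj$features
  m <- signature_model(obj$features, obj$loadings, transforms)
  m$sign_convention <- obj$sign_convention
  m$var_explained <- obj$var_explained
  m
}
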