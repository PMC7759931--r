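#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (monotone, capped at 1), targeting a global false
#' discovery rate; thin wrapper over `stats::p.adjust(method = "BH")` so
#' the screening code has a single named entry point.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Spearman correlation of each feature with lesion volume
#'
#' Rank correlation (average ranks for ties) between each feature column
#' and lesion volume; constant features yield `NA`.
#'
#' @param features data.frame or matrix of feature columns.
#' @param volume numeric vector of lesion volumes.
#' @return named vector of Spearman rho.
#' @export
spearman_volume_profile <- function(features, volume) {
  stopifnot(length(volume) >= 3)
  vapply(as.data.frame(features), function(f) {
    if (length(unique(f)) < 2) return(NA_real_)
    cor(f, volume, method = "spearman")
  }, numeric(1))
}

#' Feature-by-feature mixed-model screen
#'
#' For every real feature (on its registered transform scale) and every
#' spiked random predictor, fits the random-intercept model
#' `log(maf) ~ feature` (REML; plus `log(volume)` as an additional fixed
#' predictor when `adjust_volume = TRUE`), recording the Wald t of the
#' feature, its p-value, marginal R-squared, and — in the volume-adjusted
#' screen — the likelihood-ratio test of the feature-plus-volume model
#' against the volume-only model (both ML). Benjamini-Hochberg adjustment
#' is applied to the combined real-plus-random p-value set (the spiked
#' negative controls calibrate the multiplicity correction). When
#' `adjust_volume = FALSE`, lesion volume itself participates as one of
#' the real features.
#'
#' @param cohort data.frame from [assemble_cohort()] or
#'   [generate_cohort()]: must contain `log_maf`, `patient_id`,
#'   `log_volume` and the feature columns.
#' @param feature_names character vector of real feature columns to screen.
#' @param registry transform registry (see
#'   [default_transform_registry()]).
#' @param n_random number of spiked random predictors (half generated with
#'   patient dependence at `random_icc`, half without).
#' @param random_icc intraclass correlation of the patient-dependent half.
#' @param adjust_volume include log-volume as a fixed covariate and test
#'   features by LRT over the volume-only model.
#' @param fdr_level FDR level for the significance flag.
#' @param seed seed for the spiked predictors.
#' @return object of class `screen_result`: a data.frame sorted by
#'   adjusted p with columns `feature, is_random, t, df, p, p_adj,
#'   significant, marginal_r2` (plus `lrt_stat, lrt_p` when volume
#'   adjusted), with attributes `adjust_volume`, `fdr_level`, `skipped`
#'   (features whose transform failed, with reasons).
#' @export
screen_features <- function(cohort, feature_names, registry =
                              default_transform_registry(),
                            n_random = 100, random_icc = 0.3,
                            adjust_volume = FALSE, fdr_level = 0.05,
                            seed = 1) {
  stopifnot(all(c("log_maf", "patient_id", "log_volume") %in%
                  names(cohort)))
  if (length(unique(cohort$patient_id)) < 2)
    stop("need at least 2 patients", call. = FALSE)
  y <- cohort$log_maf
  g <- as.integer(factor(cohort$patient_id))
  ng <- max(g)
  n <- length(y)
  lv <- cohort$log_volume

  spikes <- cbind(
    spike_random_features(ceiling(n_random / 2), cohort$patient_id,
                          icc = 0, seed = seed),
    spike_random_features(floor(n_random / 2), cohort$patient_id,
                          icc = random_icc, seed = seed + 1)
  )
  colnames(spikes) <- sprintf("[random%d]", seq_len(ncol(spikes)))

  skipped <- list()
  cols <- list()
  for (nm in feature_names) {
    tr <- tryCatch(
      apply_transform(cohort[[nm]], .registry_spec(registry, nm), nm),
      error = function(e) e)
    if (inherits(tr, "error")) {
      skipped[[nm]] <- conditionMessage(tr)
    } else cols[[nm]] <- tr$values
  }
  for (nm in colnames(spikes)) cols[[nm]] <- spikes[[nm]]

  restricted_ml <- if (adjust_volume)
    .mlm_fit_fast(y, cbind(1, lv), g, ng, reml = FALSE) else NULL

  rows <- lapply(names(cols), function(nm) {
    x <- cols[[nm]]
    X <- if (adjust_volume) cbind(1, x, lv) else cbind(1, x)
    fit <- fit_mlm(y, X, g, method = "REML")
    out <- data.frame(
      feature = nm, is_random = is_random_feature(nm),
      t = fit$coefficients$t[2], df = fit$coefficients$df[2],
      p = fit$coefficients$p[2], marginal_r2 = fit$marginal_r2)
    if (adjust_volume) {
      full_ml <- .mlm_fit_fast(y, X, g, ng, reml = FALSE)
      stat <- max(2 * (full_ml$logLik - restricted_ml$logLik), 0)
      out$lrt_stat <- stat
      out$lrt_p <- pchisq(stat, df = 1, lower.tail = FALSE)
    }
    out
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj <= fdr_level
  res <- res[order(res$p_adj, res$p, res$feature), ]
  rownames(res) <- NULL
  structure(res, class = c("screen_result", "data.frame"),
            adjust_volume = adjust_volume, fdr_level = fdr_level,
            skipped = skipped)
}

#' Write a screen result as a CSV table
#'
#' Emits the screening table with the display columns (feature, t, p,
#' adjusted p, marginal R-squared, volume-adjusted flag).
#' @param x a `screen_result`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_screen_csv <- function(x, path) {
  out <- data.frame(Feature = x$feature, t.Value = x$t, p.Value = x$p,
                    Adj.p.Value = x$p_adj, R2 = x$marginal_r2,
                    Volume.adjusted = isTRUE(attr(x, "adjust_volume")))
  if (!is.null(x$lrt_stat)) {
    out$LRT <- x$lrt_stat
    out$LRT.p <- x$lrt_p
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
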