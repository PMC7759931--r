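#' Estimate the joint feature/volume covariance model
#'
#' Covariance (and means) of the transformed features together with
#' log-volume, the structure preserved by the Monte-Carlo null generator.
#' The estimate is repaired to positive semi-definiteness by clipping
#' eigenvalues at `1e-10` (the adjustment is recorded).
#'
#' @param features complete numeric matrix/data.frame of transformed
#'   features (no missing values).
#' @param volume numeric vector (log lesion volume).
#' @return list with `mean`, `cov` (features + final `volume` column),
#'   `clipped` (TRUE when PSD repair was needed), `feature_names`.
#' @export
estimate_joint_structure <- function(features, volume) {
  X <- as.matrix(features)
  if (any(is.na(X)) || any(is.na(volume)))
    stop("missing values in features or volume", call. = FALSE)
  M <- cbind(X, volume = volume)
  S <- cov(M)
  ev <- eigen(S, symmetric = TRUE)
  clipped <- any(ev$values < 1e-10)
  if (clipped) {
    vals <- pmax(ev$values, 1e-10)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    dimnames(S) <- dimnames(cov(M))
  }
  list(mean = colMeans(M), cov = S, clipped = clipped,
       feature_names = colnames(X))
}

#' Configuration for the Monte-Carlo null reference test
#'
#' @param n_datasets number of simulated null datasets (study scale 2500;
#'   desk-scale runs use 200-500).
#' @param n_features number of random features per dataset (38 when volume
#'   is removed from a 39-feature list).
#' @param include_patient_dependence add a per-patient component to the
#'   simulated features.
#' @param icc patient-level variance share when patient dependence is on.
#' @param top_k number of features selected inside each dataset.
#' @param seed integer seed.
#' @return list of class `null_sim_config`.
#' @export
null_sim_config <- function(n_datasets = 2500, n_features = 38,
                            include_patient_dependence = FALSE,
                            icc = 0.3, top_k = 5, seed = 1) {
  stopifnot(n_datasets >= 1, n_features >= 5)
  structure(list(n_datasets = n_datasets, n_features = n_features,
                 include_patient_dependence = include_patient_dependence,
                 icc = icc, top_k = top_k, seed = seed),
            class = "null_sim_config")
}

#' Simulate null feature datasets conditional on observed volume
#'
#' Draws Gaussian feature matrices with the estimated feature/volume
#' covariance, conditionally on the OBSERVED volume column, so each
#' simulated feature keeps its estimated correlation with lesion volume
#' while having zero population correlation with the response — the
#' response never enters the generator. Optionally a per-patient component
#' is mixed in at the configured intraclass correlation (the conditional
#' covariance is split between patient and visit levels, leaving the
#' marginal structure intact).
#'
#' @param structure from [estimate_joint_structure()].
#' @param volume observed log-volume vector (held fixed across datasets).
#' @param cfg a [null_sim_config()].
#' @param patient_ids required when `include_patient_dependence` is TRUE.
#' @return function `(i)` returning the i-th simulated feature matrix
#'   (deterministic in `cfg$seed` and `i`).
#' @export
simulate_null_features <- function(structure, volume, cfg,
                                   patient_ids = NULL) {
  stopifnot(inherits(cfg, "null_sim_config"))
  p_all <- ncol(structure$cov)
  fidx <- seq_len(p_all - 1)
  Sff <- structure$cov[fidx, fidx, drop = FALSE]
  Sfv <- structure$cov[fidx, p_all]
  Svv <- structure$cov[p_all, p_all]
  slope <- Sfv / Svv
  cond_mean <- outer(volume - structure$mean[p_all], slope)
  cond_mean <- sweep(cond_mean, 2, structure$mean[fidx], "+")
  Scond <- Sff - outer(slope, Sfv)
  ev <- eigen(Scond, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(fidx))
  n <- length(volume)
  k <- cfg$n_features
  if (k > length(fidx)) stop("n_features exceeds available columns",
                             call. = FALSE)
  keep <- seq_len(k)
  gint <- if (!is.null(patient_ids)) as.integer(factor(patient_ids))
          else NULL
  if (cfg$include_patient_dependence && is.null(gint))
    stop("patient_ids required for patient-dependent simulation",
         call. = FALSE)
  function(i) {
    set.seed(cfg$seed + i)
    if (cfg$include_patient_dependence) {
      npat <- max(gint)
      Zb <- (matrix(rnorm(npat * length(fidx)), npat) %*%
               t(A))[gint, , drop = FALSE]
      Ze <- matrix(rnorm(n * length(fidx)), n) %*% t(A)
      Z <- sqrt(cfg$icc) * Zb + sqrt(1 - cfg$icc) * Ze
    } else {
      Z <- matrix(rnorm(n * length(fidx)), n) %*% t(A)
    }
    out <- (cond_mean + Z)[, keep, drop = FALSE]
    colnames(out) <- structure$feature_names[keep]
    out
  }
}

#' Monte-Carlo null reference test for the top-5 / signature models
#'
#' Locates the real data's statistics in the null cloud: for the real
#' cohort and for each simulated null dataset, the per-feature
#' volume-adjusted LRT screen is run, the `top_k` best features are
#' selected (re-selected inside every null dataset, so the selection bias
#' is preserved under the null), the chosen model — the five features
#' jointly, or the first-PC signature built from them — is fitted against
#' the volume-only baseline, and its marginal R-squared and LRT statistic
#' recorded. Empirical exceedance probabilities use the add-one rule
#' `p = (1 + #{null >= real}) / (n_datasets + 1)`, so they are never 0.
#'
#' @param cohort data.frame with `log_maf`, `patient_id`, `log_volume` and
#'   the feature columns.
#' @param feature_names real feature columns entering the structure
#'   estimate (volume excluded).
#' @param cfg a [null_sim_config()].
#' @param builder `"five-features"` (joint fixed effects) or
#'   `"signature"` (first-PC signature of the selected features).
#' @param registry transform registry applied to the real features before
#'   structure estimation and modelling.
#' @param reselect re-run the top-k selection inside each null dataset.
#'   Disabling this biases the test anti-conservatively and is refused
#'   unless `allow_no_reselect = TRUE`.
#' @param allow_no_reselect override guard for `reselect = FALSE`.
#' @return object of class `null_sim_result`: list with `real` (R2 and
#'   LRT statistic), `null` (data.frame per dataset), `p_r2`, `p_lrt`,
#'   `builder`, `cfg`.
#' @export
null_reference_test <- function(cohort, feature_names, cfg = null_sim_config(),
                                builder = c("five-features", "signature"),
                                registry = default_transform_registry(),
                                reselect = TRUE,
                                allow_no_reselect = FALSE) {
  builder <- match.arg(builder)
  if (!reselect && !allow_no_reselect)
    stop(paste("reselect = FALSE makes the null test anti-conservative;",
               "set allow_no_reselect = TRUE to override"), call. = FALSE)
  y <- cohort$log_maf
  gint <- as.integer(factor(cohort$patient_id))
  ng <- max(gint)
  n <- length(y)
  lv <- cohort$log_volume

  # transformed real features
  Z <- matrix(NA_real_, n, length(feature_names),
              dimnames = list(NULL, feature_names))
  for (nm in feature_names) {
    Z[, nm] <- apply_transform(cohort[[nm]],
                               .registry_spec(registry, nm), nm)$values
  }

  restricted <- .mlm_fit_fast(y, cbind(1, lv), gint, ng, reml = FALSE)
  if (!is.finite(restricted$logLik))
    stop("volume-only baseline fit failed", call. = FALSE)

  score_dataset <- function(feats) {
    # per-feature volume-adjusted LRT, pick top_k, fit chosen model
    k <- ncol(feats)
    ll <- vapply(seq_len(k), function(j) {
      .mlm_fit_fast(y, cbind(1, feats[, j], lv), gint, ng,
                    reml = FALSE)$logLik
    }, numeric(1))
    ord <- order(-ll, colnames(feats))
    top <- ord[seq_len(min(cfg$top_k, k))]
    Xtop <- feats[, top, drop = FALSE]
    if (builder == "signature") {
      Zs <- scale(Xtop)
      evv <- eigen(cov(Zs), symmetric = TRUE)
      sig <- as.vector(Zs %*% evv$vectors[, 1])
      Xm <- cbind(1, sig, lv)
    } else {
      Xm <- cbind(1, Xtop, lv)
    }
    fit <- .mlm_fit_fast(y, Xm, gint, ng, reml = FALSE)
    c(r2 = fit$marginal_r2,
      lrt = max(2 * (fit$logLik - restricted$logLik), 0))
  }

  real_stat <- score_dataset(Z)

  structure_est <- estimate_joint_structure(Z, lv)
  gen <- simulate_null_features(structure_est, lv, cfg,
                                patient_ids = cohort$patient_id)
  if (reselect) {
    null_stats <- t(vapply(seq_len(cfg$n_datasets),
                           function(i) score_dataset(gen(i)),
                           numeric(2)))
  } else {
    fixed_top <- NULL
    null_stats <- t(vapply(seq_len(cfg$n_datasets), function(i) {
      feats <- gen(i)[, seq_len(cfg$top_k), drop = FALSE]
      Xm <- if (builder == "signature") {
        Zs <- scale(feats)
        evv <- eigen(cov(Zs), symmetric = TRUE)
        cbind(1, as.vector(Zs %*% evv$vectors[, 1]), lv)
      } else cbind(1, feats, lv)
      fit <- .mlm_fit_fast(y, Xm, gint, ng, reml = FALSE)
      c(r2 = fit$marginal_r2,
        lrt = max(2 * (fit$logLik - restricted$logLik), 0))
    }, numeric(2)))
  }
  nd <- cfg$n_datasets
  structure(list(
    real = real_stat,
    null = data.frame(dataset = seq_len(nd), r2 = null_stats[, 1],
                      lrt = null_stats[, 2]),
    p_r2 = (1 + sum(null_stats[, 1] >= real_stat["r2"])) / (nd + 1),
    p_lrt = (1 + sum(null_stats[, 2] >= real_stat["lrt"])) / (nd + 1),
    builder = builder, cfg = cfg),
    class = "null_sim_result")
}

#' Write the null-test scatter data (one row per dataset plus the real pair)
#' @param x a `null_sim_result`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_nullsim_csv <- function(x, path) {
  df <- rbind(
    data.frame(dataset = x$null$dataset, r2 = x$null$r2, lrt = x$null$lrt,
               real = FALSE),
    data.frame(dataset = NA_integer_, r2 = x$real["r2"],
               lrt = x$real["lrt"], real = TRUE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
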