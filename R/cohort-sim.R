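#' Configuration of the synthetic longitudinal cohort generator
#'
#' Defines the generative conditions the analysis assumes: a small
#' longitudinal oncology cohort (default 15 patients with 1-12 imaging
#' visits each, ~70 visits in expectation) whose radiomic features are
#' strongly intercorrelated and correlated with lesion volume, whose
#' log(ctDNA maf) is driven by log lesion volume plus a patient random
#' intercept, whose LDH is quadratically related to log(maf), and whose
#' blood draws are offset from imaging dates by a median of ~10 days.
#'
#' @param n_patients number of patients (>= 2).
#' @param visit_range integer range of visits per patient; counts are drawn
#'   as `1 + Poisson(visit_mean - 1)` truncated to the range.
#' @param visit_mean mean visits per patient (default 70/15).
#' @param beta0,beta_volume intercept and slope of log(maf) on log(volume
#'   in mm^3).
#' @param icc_patient intraclass correlation of the response attributable
#'   to the patient random intercept, in \[0, 1).
#' @param sigma_resid residual standard deviation of log(maf).
#' @param feature_cov target correlation matrix of the transformed features
#'   plus the log-volume column (its column must be named `"Volume"`);
#'   defaults to a single-factor structure over the canonical 39 features.
#' @param feature_icc patient-level variance share of each feature.
#' @param beta_features optional named numeric vector of slopes of
#'   log(maf) on the latent (transform-scale, standardized) feature values
#'   — a planted feature signal beyond lesion volume. Default `NULL`: the
#'   response depends on the features only through their correlation with
#'   volume.
#' @param ldh_coefs three coefficients `(a0, a1, a2)` of
#'   `LDH = a0 + a1 log(maf) + a2 log(maf)^2 + noise`.
#' @param ldh_sigma LDH noise s.d. (U/L).
#' @param blood_offset_meanlog,blood_offset_sdlog parameters of the
#'   discretized lognormal absolute blood-imaging offset in days
#'   (defaults: median 10, calibrated to an interquartile spread of ~(4, 34)
#'   days).
#' @param maf_floor,maf_ceiling clipping bounds keeping maf in (0, 1\].
#' @param seed integer seed.
#' @return object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 15,
                              visit_range = c(1, 12),
                              visit_mean = 70 / 15,
                              beta0 = -11,
                              beta_volume = 0.8,
                              icc_patient = 0.4,
                              sigma_resid = 0.8,
                              feature_cov = default_feature_cov(),
                              feature_icc = 0.3,
                              beta_features = NULL,
                              ldh_coefs = c(800, 180, 12),
                              ldh_sigma = 160,
                              blood_offset_meanlog = log(10),
                              blood_offset_sdlog = log(34 / 4) / (2 * 0.6745),
                              maf_floor = 1e-6,
                              maf_ceiling = 1,
                              seed = 1) {
  stopifnot(n_patients >= 2, icc_patient >= 0, icc_patient < 1,
            sigma_resid > 0, length(ldh_coefs) == 3)
  if (!isSymmetric(unname(feature_cov), tol = 1e-8))
    stop("feature_cov must be symmetric", call. = FALSE)
  ev <- eigen(feature_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("feature_cov is not positive semi-definite (eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  if (!"Volume" %in% colnames(feature_cov))
    stop("feature_cov must include a 'Volume' column", call. = FALSE)
  structure(list(
    n_patients = n_patients, visit_range = visit_range,
    visit_mean = visit_mean, beta0 = beta0, beta_volume = beta_volume,
    icc_patient = icc_patient, sigma_resid = sigma_resid,
    feature_cov = feature_cov, feature_icc = feature_icc,
    beta_features = beta_features,
    ldh_coefs = ldh_coefs, ldh_sigma = ldh_sigma,
    blood_offset_meanlog = blood_offset_meanlog,
    blood_offset_sdlog = blood_offset_sdlog,
    maf_floor = maf_floor, maf_ceiling = maf_ceiling, seed = seed),
    class = "cohort_sim_config")
}

#' Default feature correlation structure
#'
#' Single-factor correlation matrix over the canonical 39 feature names:
#' feature i has loading `l_i` on a shared latent factor (loadings cycle
#' over 0.4-0.85), and the log-volume column loads at 0.8, so features are
#' strongly intercorrelated and correlated with lesion volume — the
#' structure the volume-adjusted analyses must untangle.
#'
#' @param feature_names names of the feature columns.
#' @param volume_loading factor loading of log-volume.
#' @return correlation matrix with a final `Volume` column.
#' @export
default_feature_cov <- function(feature_names =
                                  setdiff(radiomic_feature_names(),
                                          "Volume"),
                                volume_loading = 0.8) {
  k <- length(feature_names)
  loadings <- c(rep(c(0.4, 0.55, 0.7, 0.85), length.out = k),
                volume_loading)
  C <- outer(loadings, loadings)
  diag(C) <- 1
  colnames(C) <- rownames(C) <- c(feature_names, "Volume")
  C
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a cohort under the configured generative model. Features (plus the
#' latent log-volume) are multivariate Gaussian via a Cholesky factor of the
#' target correlation matrix, with patient dependence added as a shared
#' per-patient component scaled to the feature ICC. The response is
#' `log(maf) = beta0 + beta_volume * log(volume) + b_patient + eps` with
#' `Var(b) / (Var(b) + Var(eps)) = icc_patient`; maf is exponentiated and
#' clipped to (0, 1]. Blood samples are offset from visit dates by a signed
#' discretized lognormal interval and carry sWGS values, plus TAm-Seq
#' values where the sWGS tumor fraction falls below its 3% limit of
#' detection. LDH is generated quadratically in log(maf).
#'
#' Feature columns are emitted on their natural scales: the correlated
#' Gaussian draw lives on each feature's registered transform scale and is
#' mapped back through the inverse transform (e.g. exponentiated for
#' log-scale features), so applying the registry during analysis recovers
#' the target correlation structure exactly.
#'
#' @param cfg a [cohort_sim_config()].
#' @param registry transform registry used to back-transform the feature
#'   columns onto natural scales.
#' @return list with `cohort` (per-visit modelling table), `features`
#'   (visits x named features), `blood` (blood-sample table) and `truth`
#'   (realized coefficients, per-patient intercepts, noise-free response).
#' @export
generate_cohort <- function(cfg = cohort_sim_config(),
                            registry = default_transform_registry()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  npat <- cfg$n_patients
  nv <- pmin(pmax(1 + rpois(npat, cfg$visit_mean - 1),
                  cfg$visit_range[1]), cfg$visit_range[2])
  n <- sum(nv)
  pid <- rep(seq_len(npat), nv)

  # correlated Gaussian block: features + log-volume
  C <- cfg$feature_cov
  k <- ncol(C)
  L <- chol(C + diag(1e-10, k))
  B <- matrix(rnorm(npat * k), npat, k) %*% L    # patient-level component
  E <- matrix(rnorm(n * k), n, k) %*% L          # visit-level component
  Zl <- sqrt(cfg$feature_icc) * B[pid, , drop = FALSE] +
    sqrt(1 - cfg$feature_icc) * E
  colnames(Zl) <- colnames(C)

  # lesion volume: log-normal around ~20 mL
  log_volume <- 9.9 + 0.8 * Zl[, "Volume"]
  volume_mm3 <- exp(log_volume)

  # response
  sd_b <- cfg$sigma_resid * sqrt(cfg$icc_patient / (1 - cfg$icc_patient))
  b <- rnorm(npat, sd = sd_b)
  mu <- cfg$beta0 + cfg$beta_volume * log_volume
  if (!is.null(cfg$beta_features)) {
    bf <- cfg$beta_features
    if (is.null(names(bf)) || !all(names(bf) %in% colnames(Zl)))
      stop("beta_features must be named after feature columns",
           call. = FALSE)
    mu <- mu + as.vector(Zl[, names(bf), drop = FALSE] %*% bf)
  }
  eps <- rnorm(n, sd = cfg$sigma_resid)
  log_maf_raw <- mu + b[pid] + eps
  maf <- pmin(pmax(exp(log_maf_raw), cfg$maf_floor), cfg$maf_ceiling)

  # LDH quadratic in log(maf)
  lm_ <- log(maf)
  ldh <- cfg$ldh_coefs[1] + cfg$ldh_coefs[2] * lm_ +
    cfg$ldh_coefs[3] * lm_^2 + rnorm(n, sd = cfg$ldh_sigma)

  # visit dates: ~2-monthly imaging
  dates <- unlist(lapply(nv, function(m) {
    cumsum(c(0, round(rlnorm(max(m - 1, 0), log(60), 0.25))))
  }))
  base_date <- as.Date("2020-01-01")
  visit_date <- base_date + dates

  feature_names <- setdiff(colnames(C), "Volume")
  features <- as.data.frame(lapply(feature_names, function(nm)
    .inverse_transform(Zl[, nm], .registry_spec(registry, nm))))
  names(features) <- feature_names
  features <- cbind(data.frame(patient_id = pid, date = visit_date),
                    features)
  features$Volume <- volume_mm3 / 1000   # mL, as reported

  # blood draws: signed lognormal offset from each visit
  off <- round(rlnorm(n, cfg$blood_offset_meanlog, cfg$blood_offset_sdlog))
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  blood_date <- visit_date + sgn * off
  swgs <- maf
  blood <- data.frame(patient_id = pid, date = blood_date,
                      assay = "sWGS", maf = swgs, ldh = ldh)
  low <- swgs < 0.03
  if (any(low)) {
    blood <- rbind(blood, data.frame(
      patient_id = pid[low], date = blood_date[low],
      assay = "TAmSeq", maf = maf[low], ldh = ldh[low]))
  }
  blood <- blood[order(blood$patient_id, blood$date), ]
  rownames(blood) <- NULL

  cohort <- data.frame(patient_id = pid, date = visit_date, maf = maf,
                       log_maf = log(maf), ldh = ldh,
                       volume_mm3 = volume_mm3, log_volume = log_volume)
  cohort <- cbind(cohort,
                  features[, c(feature_names, "Volume"), drop = FALSE])

  truth <- list(beta0 = cfg$beta0, beta_volume = cfg$beta_volume,
                beta_features = cfg$beta_features,
                blood_offsets = sgn * off,
                patient_intercepts = b, noise_free_response = mu + b[pid],
                sigma_resid = cfg$sigma_resid, sd_patient = sd_b,
                seed = cfg$seed)
  list(cohort = cohort, features = features, blood = blood, truth = truth)
}

# Map a standard-Gaussian draw onto a feature's natural scale so that its
# registered transform recovers an affine function of the draw. Centers and
# scales are chosen to yield plausible magnitudes; correlations on the
# transform scale are unaffected by the affine choice.
.inverse_transform <- function(z, spec) {
  switch(spec$kind,
    identity = z,
    log = exp(0.5 * z + 2),
    log_shift = exp(0.5 * z + 2) - spec$shift,
    loglog_shift = exp(exp(0.3 * z + 0.75) - spec$shift))
}

#' Spike in independent random predictor columns
#'
#' Generates `n` Gaussian predictor columns independent of every real
#' feature and of the response, used as negative controls calibrating the
#' FDR screen and the selection stopping rules. With `icc > 0` each column
#' carries a shared per-patient component giving it that patient-level
#' variance share. Columns are named with the reserved prefix
#' `"[random<i>]"`.
#'
#' @param n number of columns.
#' @param patient_ids patient id per row.
#' @param icc patient-level variance share in \[0, 1).
#' @param seed integer seed.
#' @return data.frame of `n` spiked columns.
#' @export
spike_random_features <- function(n = 100, patient_ids, icc = 0, seed = 1) {
  stopifnot(n >= 1, icc >= 0, icc < 1)
  set.seed(seed)
  g <- as.integer(factor(patient_ids))
  npat <- max(g)
  nr <- length(g)
  B <- matrix(rnorm(npat * n), npat, n)
  E <- matrix(rnorm(nr * n), nr, n)
  M <- sqrt(icc) * B[g, , drop = FALSE] + sqrt(1 - icc) * E
  colnames(M) <- sprintf("[random%d]", seq_len(n))
  as.data.frame(M)
}

#' Is a column name a spiked random predictor?
#' @param x character vector of feature names.
#' @return logical vector.
#' @export
is_random_feature <- function(x) grepl("^\\[random", x)
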