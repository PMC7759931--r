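#' Choose the maf value between paired assays at one date
#'
#' Shallow whole-genome sequencing (sWGS, tumor fraction via copy-number
#' analysis) loses sensitivity below a 3% tumor fraction; below that limit
#' of detection the targeted TAm-Seq value is preferred when available. An
#' sWGS value of exactly 0.03 is retained (the rule is strictly "< 3%").
#'
#' @param swgs sWGS tumor fraction in \[0, 1\], or `NA`.
#' @param tamseq TAm-Seq mutant allele fraction in \[0, 1\], or `NA`.
#' @param lod sWGS limit of detection (default 0.03).
#' @return list with `maf`, `assay` ("sWGS" or "TAmSeq") and `below_lod`
#'   (TRUE when an sWGS value below the limit had no TAm-Seq backup).
#' @export
choose_assay <- function(swgs = NA, tamseq = NA, lod = 0.03) {
  if (is.na(swgs) && is.na(tamseq))
    stop("no assay value available", call. = FALSE)
  if (!is.na(swgs) && swgs >= lod)
    return(list(maf = swgs, assay = "sWGS", below_lod = FALSE))
  if (!is.na(tamseq))
    return(list(maf = tamseq, assay = "TAmSeq", below_lod = FALSE))
  list(maf = swgs, assay = "sWGS", below_lod = TRUE)
}

#' Interpolate maf at an imaging visit date
#'
#' Linear interpolation on the maf scale between the two blood samples
#' bracketing the visit date; an exact-date sample is returned as is.
#' Outside the sampled range the nearest sample's value is carried over and
#' flagged as extrapolated.
#'
#' @param sample_dates dates (Date or numeric days) of the patient's blood
#'   samples.
#' @param sample_maf maf values at those dates.
#' @param visit_date the imaging date.
#' @return list with `maf` and `extrapolated` flag.
#' @export
interpolate_maf <- function(sample_dates, sample_maf, visit_date) {
  if (length(sample_dates) == 0) stop("no blood samples", call. = FALSE)
  stopifnot(length(sample_dates) == length(sample_maf))
  d <- as.numeric(sample_dates)
  v <- as.numeric(visit_date)
  o <- order(d)
  d <- d[o]; m <- sample_maf[o]
  if (v <= d[1]) {
    return(list(maf = m[1], extrapolated = v < d[1]))
  }
  if (v >= d[length(d)]) {
    return(list(maf = m[length(m)], extrapolated = v > d[length(d)]))
  }
  hit <- which(d == v)
  if (length(hit)) return(list(maf = mean(m[hit]), extrapolated = FALSE))
  i <- findInterval(v, d)
  w <- (v - d[i]) / (d[i + 1] - d[i])
  list(maf = (1 - w) * m[i] + w * m[i + 1], extrapolated = FALSE)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with a
#' 95% confidence interval via the Fisher z-transform of the CCC.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param conf_level confidence level.
#' @return list with `estimate`, `lower`, `upper`, `n`.
#' @export
lin_ccc <- function(x, y, conf_level = 0.95) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  # Lin's original estimator uses population (1/n) moments
  sx <- mean((x - mean(x))^2); sy <- mean((y - mean(y))^2)
  if (sx == 0 && sy == 0) stop("zero variance in both variables",
                               call. = FALSE)
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  ccc <- 2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
  z <- atanh(min(max(ccc, -1 + 1e-12), 1 - 1e-12))
  sez <- 1 / sqrt(n - 2)
  q <- qnorm(1 - (1 - conf_level) / 2)
  list(estimate = ccc, lower = tanh(z - q * sez),
       upper = tanh(z + q * sez), n = n)
}

#' Convert a fractional diameter change to a fractional volume change
#'
#' RECIST 1.1 thresholds are diameter-based; assuming geometric similarity
#' the corresponding volume change is `(1 + d)^3 - 1`, e.g. a +20% diameter
#' change maps to +72.8% volume and a -30% change to -65.7%.
#'
#' @param d fractional diameter change (> -1).
#' @return fractional volume change.
#' @export
diameter_to_volume_threshold <- function(d) {
  stopifnot(all(d > -1))
  (1 + d)^3 - 1
}

#' Categorize a lesion volume change
#'
#' Volume-change categories derived from the RECIST 1.1 diameter
#' thresholds: relative change `r = current/baseline - 1`; `r > 0.73` is a
#' large increase (progression-equivalent), `r < -0.66` a large decrease
#' (response-equivalent), the remainder small increases/decreases; exactly
#' zero change is labelled "no change".
#'
#' @param baseline_vol,current_vol volumes (> 0 baseline, >= 0 current).
#' @param up,down the large-change thresholds (defaults 0.73 and -0.66).
#' @return character category.
#' @export
categorize_volume_change <- function(baseline_vol, current_vol,
                                     up = 0.73, down = -0.66) {
  if (baseline_vol <= 0 || current_vol < 0)
    stop("volumes must be positive", call. = FALSE)
  r <- current_vol / baseline_vol - 1
  if (r > up) "large increase"
  else if (r > 0) "small increase"
  else if (r == 0) "no change"
  else if (r >= down) "small decrease"
  else "large decrease"
}

#' Assemble the per-visit cohort table
#'
#' Joins imaging visits with blood-derived measurements: per (patient,
#' visit date), the maf interpolated from the patient's blood samples (the
#' assay choice rule applied per sample date first), the LDH value from the
#' nearest blood draw, the lesion volume, and optionally the extracted
#' feature columns. maf values of 0 are floored at `maf_floor` so the log
#' response is finite.
#'
#' @param blood data.frame: `patient_id, date, assay, maf` (+ optional
#'   `ldh`). Rows with assay `"sWGS"` and `"TAmSeq"` on the same date are
#'   merged by [choose_assay()].
#' @param visits data.frame: `patient_id, date, volume_mm3`.
#' @param features optional data.frame keyed by `patient_id, date` with
#'   feature columns.
#' @param maf_floor lower floor applied to maf before taking logs.
#' @return data.frame, one row per (patient, visit date): `patient_id,
#'   date, maf, log_maf, extrapolated, ldh, volume_mm3, log_volume` plus
#'   feature columns.
#' @export
assemble_cohort <- function(blood, visits, features = NULL,
                            maf_floor = 1e-6) {
  stopifnot(all(c("patient_id", "date", "assay", "maf") %in% names(blood)))
  stopifnot(all(c("patient_id", "date", "volume_mm3") %in% names(visits)))
  # resolve assay pairs per (patient, date)
  key <- interaction(blood$patient_id, as.character(blood$date),
                     drop = TRUE)
  resolved <- do.call(rbind, lapply(split(blood, key), function(b) {
    sw <- b$maf[b$assay == "sWGS"]
    ts <- b$maf[b$assay == "TAmSeq"]
    ch <- choose_assay(if (length(sw)) sw[1] else NA,
                       if (length(ts)) ts[1] else NA)
    data.frame(patient_id = b$patient_id[1], date = b$date[1],
               maf = ch$maf, assay = ch$assay, below_lod = ch$below_lod,
               ldh = if ("ldh" %in% names(b)) b$ldh[1] else NA_real_)
  }))
  out <- lapply(seq_len(nrow(visits)), function(r) {
    pid <- visits$patient_id[r]
    vd <- visits$date[r]
    bs <- resolved[resolved$patient_id == pid, , drop = FALSE]
    if (nrow(bs) == 0)
      stop(sprintf("no blood samples for patient %s", pid), call. = FALSE)
    ip <- interpolate_maf(bs$date, bs$maf, vd)
    ldh <- if (all(is.na(bs$ldh))) NA_real_ else {
      bs2 <- bs[!is.na(bs$ldh), ]
      bs2$ldh[which.min(abs(as.numeric(bs2$date) - as.numeric(vd)))]
    }
    maf <- max(ip$maf, maf_floor)
    data.frame(patient_id = pid, date = vd, maf = maf,
               log_maf = log(maf), extrapolated = ip$extrapolated,
               ldh = ldh, volume_mm3 = visits$volume_mm3[r],
               log_volume = log(visits$volume_mm3[r]))
  })
  cohort <- do.call(rbind, out)
  if (!is.null(features)) {
    fkey <- paste(features$patient_id, as.character(features$date))
    ckey <- paste(cohort$patient_id, as.character(cohort$date))
    m <- match(ckey, fkey)
    fcols <- setdiff(names(features), c("patient_id", "date"))
    cohort <- cbind(cohort, features[m, fcols, drop = FALSE])
    rownames(cohort) <- NULL
  }
  cohort
}
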