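#' The canonical 39-feature set
#'
#' Names of the default radiomic feature set: 6 histogram, 2 shape, 6 GLCM,
#' 3 NGLDM, 11 GLRLM and 11 GLZLM features. [extract_all()] computes a
#' small superset (Min, Max) and flags membership in this canonical set via
#' the `in_default_set` attribute.
#' @return character vector of 39 feature names.
#' @export
radiomic_feature_names <- function() {
  c("Mean", "StdDev", "Skewness", "Kurtosis", "Entropy_h", "Uniformity",
    "Volume", "Sphericity",
    "Homogeneity", "Energy", "Contrast", "Correlation", "Entropy",
    "Dissimilarity",
    "Coarseness", "Busyness", "Contrast_NGLDM",
    "SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
    "GLNUr", "RLNU", "RP",
    "SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE",
    "GLNUz", "ZLNU", "ZP")
}

#' Default extraction configuration
#'
#' 128 gray levels over \[-400, 400\] HU for the co-occurrence, run-length,
#' neighborhood-difference and histogram statistics; 32 levels over the same
#' range for zone-length features; spatial resampling to 1 mm isotropic
#' voxels; lesions below 1 cm^3 excluded unless overridden.
#' @param bins,zone_bins gray levels for the fine/coarse discretization.
#' @param lo,hi absolute HU range.
#' @param resample_mm target isotropic spacing (NULL to skip resampling).
#' @param min_volume_ml minimum lesion volume in mL.
#' @param override_min_volume set TRUE to extract sub-threshold lesions.
#' @return list of configuration values.
#' @export
extraction_config <- function(bins = 128, zone_bins = 32, lo = -400,
                              hi = 400, resample_mm = 1.0,
                              min_volume_ml = 1.0,
                              override_min_volume = FALSE) {
  list(bins = bins, zone_bins = zone_bins, lo = lo, hi = hi,
       resample_mm = resample_mm, min_volume_ml = min_volume_ml,
       override_min_volume = override_min_volume)
}

#' Extract the full radiomic feature vector from a masked volume
#'
#' Applies the standard extraction chain: the 1 cm^3 volume rule (checked on
#' the native grid), resampling to isotropic voxels, discretization at the
#' fine (128) and coarse (32) bin settings, then the histogram/shape, GLCM,
#' NGLDM, GLRLM (fine bins) and GLZLM (coarse bins) families.
#'
#' @param volume 3D numeric array of HU intensities.
#' @param mask logical/0-1 array, same grid.
#' @param spacing voxel spacing in mm.
#' @param config list from [extraction_config()].
#' @return named numeric vector with the computed features; attributes
#'   `provenance` (bin specs, resampling) and `in_default_set` (logical per
#'   entry, TRUE for the canonical 39).
#' @export
extract_all <- function(volume, mask, spacing, config = extraction_config()) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  vol_ml <- sum(mask) * prod(spacing) / 1000
  if (vol_ml < config$min_volume_ml && !config$override_min_volume)
    stop(sprintf(
      "lesion volume %.3f mL is below the %.0f cm^3 inclusion threshold (set override_min_volume = TRUE to force extraction)",
      vol_ml, config$min_volume_ml), call. = FALSE)
  if (!is.null(config$resample_mm)) {
    rs <- resample_isotropic(volume, mask, spacing, config$resample_mm)
    volume <- rs$volume; mask <- rs$mask; spacing <- rs$spacing
  }
  spec_fine <- discretization_spec(config$bins, config$lo, config$hi)
  spec_zone <- discretization_spec(config$zone_bins, config$lo, config$hi)
  lab_fine <- discretize(volume, mask, spec_fine)
  lab_zone <- discretize(volume, mask, spec_zone)
  fv <- c(histogram_shape_features(volume, mask, spacing, spec_fine),
          glcm_features(lab_fine),
          ngldm_features(lab_fine),
          glrlm_features(lab_fine),
          glzlm_features(lab_zone))
  attr(fv, "provenance") <- list(
    bins = config$bins, zone_bins = config$zone_bins,
    range_hu = c(config$lo, config$hi),
    resample_mm = config$resample_mm,
    native_volume_ml = vol_ml)
  attr(fv, "in_default_set") <- names(fv) %in% radiomic_feature_names()
  fv
}

#' Sliding-window feature map
#'
#' Computes a chosen (non-shape) feature on the 3x3x3 window (radius 1
#' voxel) around every in-mask voxel, window intersected with the mask.
#' Windows holding fewer than 2 in-mask voxels give `NA`.
#'
#' @inheritParams extract_all
#' @param feature one feature name (histogram or texture family; shape
#'   features are not mappable).
#' @param radius window radius in voxels.
#' @return numeric array of the feature map (`NA` outside the mask).
#' @export
feature_map <- function(volume, mask, spacing, feature, radius = 1,
                        config = extraction_config()) {
  if (feature %in% c("Volume", "Sphericity"))
    stop("shape features are not mappable", call. = FALSE)
  mask <- mask > 0
  d <- dim(volume)
  out <- array(NA_real_, d)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    ii <- max(1, i - radius):min(d[1], i + radius)
    jj <- max(1, j - radius):min(d[2], j + radius)
    kk <- max(1, k - radius):min(d[3], k + radius)
    wvol <- volume[ii, jj, kk, drop = FALSE]
    wmask <- mask[ii, jj, kk, drop = FALSE]
    if (sum(wmask) < 2) next
    out[i, j, k] <- .window_feature(wvol, wmask, spacing, feature, config)
  }
  out
}

.window_feature <- function(wvol, wmask, spacing, feature, config) {
  spec_fine <- discretization_spec(config$bins, config$lo, config$hi)
  spec_zone <- discretization_spec(config$zone_bins, config$lo, config$hi)
  hist_names <- c("Mean", "StdDev", "Skewness", "Kurtosis", "Min", "Max",
                  "Entropy_h", "Uniformity")
  val <- tryCatch({
    if (feature %in% hist_names) {
      histogram_shape_features(wvol, wmask, spacing, spec_fine)[[feature]]
    } else if (feature %in% c("Homogeneity", "Energy", "Contrast",
                              "Correlation", "Entropy", "Dissimilarity")) {
      glcm_features(discretize(wvol, wmask, spec_fine))[[feature]]
    } else if (feature %in% c("Coarseness", "Busyness", "Contrast_NGLDM")) {
      ngldm_features(discretize(wvol, wmask, spec_fine))[[feature]]
    } else if (feature %in% c("SRE", "LRE", "LGRE", "HGRE", "SRLGE",
                              "SRHGE", "LRLGE", "LRHGE", "GLNUr", "RLNU",
                              "RP")) {
      glrlm_features(discretize(wvol, wmask, spec_fine))[[feature]]
    } else if (feature %in% c("SZE", "LZE", "LGZE", "HGZE", "SZLGE",
                              "SZHGE", "LZLGE", "LZHGE", "GLNUz", "ZLNU",
                              "ZP")) {
      glzlm_features(discretize(wvol, wmask, spec_zone))[[feature]]
    } else stop(sprintf("unknown feature '%s'", feature), call. = FALSE)
  }, error = function(e) NA_real_)
  val
}

#' Select the lesion to track across visits
#'
#' Returns the lesion attaining the greatest volume at any time-point; this
#' single lesion is then tracked across all visits. Ties are broken by the
#' earliest visit at which the maximum is attained, then by lowest lesion
#' id.
#'
#' @param lesion_volumes data.frame with columns `lesion_id`, `visit` (a
#'   sortable time index or date) and `volume`.
#' @return the selected lesion id.
#' @export
select_largest_lesion <- function(lesion_volumes) {
  stopifnot(all(c("lesion_id", "visit", "volume") %in%
                  names(lesion_volumes)))
  if (nrow(lesion_volumes) == 0) stop("no lesion observations",
                                      call. = FALSE)
  vmax <- max(lesion_volumes$volume)
  cand <- lesion_volumes[lesion_volumes$volume == vmax, , drop = FALSE]
  cand <- cand[order(cand$visit, cand$lesion_id), , drop = FALSE]
  cand$lesion_id[1]
}
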