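#' Read a NIfTI volume/mask pair
#'
#' Reads an intensity volume and an aligned binary lesion mask, checking
#' that the grids match. Mask values other than 0/1 (e.g. 0/255 exports)
#' are normalized to 0/1 with a warning.
#'
#' @param volume_path,mask_path paths to NIfTI files.
#' @return list with `volume`, `mask` (logical) and `spacing` (mm).
#' @export
read_nifti_pair <- function(volume_path, mask_path) {
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  if (!all(dim(vol) == dim(msk)))
    stop("volume and mask grids do not match", call. = FALSE)
  spacing <- RNifti::pixdim(vol)[1:3]
  mv <- unique(as.vector(msk))
  if (!all(mv %in% c(0, 1))) {
    warning("mask values are not 0/1; normalizing (positive -> 1)")
  }
  list(volume = array(as.numeric(vol), dim(vol)),
       mask = array(as.vector(msk) > 0, dim(msk)),
       spacing = as.numeric(spacing))
}

#' Write a volume (or feature map) as NIfTI
#' @param volume 3D numeric/logical array.
#' @param spacing voxel spacing in mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(volume, spacing, path) {
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read the longitudinal tables (blood samples and imaging visits)
#'
#' Blood CSV columns: `patient_id, date, assay, maf` and optionally `ldh`;
#' visits CSV columns: `patient_id, date, volume_mm3` (plus free columns).
#' Dates must be ISO-8601 (`YYYY-MM-DD`); malformed dates are reported with
#' their row numbers.
#'
#' @param blood_path,visits_path CSV paths.
#' @return list with `blood` and `visits` data.frames (dates as `Date`).
#' @export
read_tables <- function(blood_path, visits_path) {
  blood <- read.csv(blood_path, stringsAsFactors = FALSE)
  visits <- read.csv(visits_path, stringsAsFactors = FALSE)
  for (nm in c("patient_id", "date", "assay", "maf")) {
    if (!nm %in% names(blood))
      stop(sprintf("blood table lacks column '%s'", nm), call. = FALSE)
  }
  for (nm in c("patient_id", "date", "volume_mm3")) {
    if (!nm %in% names(visits))
      stop(sprintf("visits table lacks column '%s'", nm), call. = FALSE)
  }
  blood$date <- .parse_dates(blood$date, "blood")
  visits$date <- .parse_dates(visits$date, "visits")
  if (any(blood$maf < 0 | blood$maf > 1, na.rm = TRUE))
    stop("maf values must lie in [0, 1]", call. = FALSE)
  list(blood = blood, visits = visits)
}

.parse_dates <- function(x, table_name) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s table: malformed date '%s' in row %d",
                 table_name, x[bad[1]], bad[1]), call. = FALSE)
  d
}
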