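#' Histogram and shape features of a masked volume
#'
#' First-order statistics on the raw in-mask intensities (population
#' moments): Mean, StdDev, Skewness (`m3 / m2^{3/2}`), Kurtosis
#' (`m4 / m2^2`, not excess), Min, Max; histogram statistics on the binned
#' intensities: Entropy_h (Shannon entropy, natural log) and Uniformity
#' (`sum p^2`); and shape: Volume (mL, voxel count times voxel volume) and
#' Sphericity `pi^{1/3} (6 V)^{2/3} / A` with `A` the exposed voxel-face
#' surface area (an approximation; no meshing).
#'
#' @param volume 3D numeric array (HU).
#' @param mask logical/0-1 array, same dimensions.
#' @param spacing voxel spacing in mm (length 3).
#' @param spec [discretization_spec()] used for the histogram statistics.
#' @return named numeric vector.
#' @export
histogram_shape_features <- function(volume, mask, spacing = c(1, 1, 1),
                                     spec = discretization_spec()) {
  mask <- mask > 0
  v <- volume[mask]
  if (length(v) < 2) stop("mask must contain at least 2 voxels",
                          call. = FALSE)
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  sdev <- sqrt(m2)
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 else NA_real_
  lab <- discretize(volume, mask, spec)
  p <- tabulate(lab[mask], nbins = spec$n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  vol_ml <- n * prod(spacing) / 1000
  A <- .surface_area(mask, spacing)
  vol_mm3 <- n * prod(spacing)
  c(Mean = m, StdDev = sdev, Skewness = skew, Kurtosis = kurt,
    Min = min(v), Max = max(v),
    Entropy_h = -sum(p * log(p)), Uniformity = sum(p^2),
    Volume = vol_ml,
    Sphericity = pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / A)
}

# Exposed voxel-face surface area in mm^2.
.surface_area <- function(mask, spacing) {
  mask <- mask > 0
  d <- dim(mask)
  area <- 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  for (ax in 1:3) {
    for (sgn in c(1L, -1L)) {
      off <- c(0L, 0L, 0L); off[ax] <- sgn
      # neighbor in-mask indicator, FALSE outside the grid
      nb <- array(FALSE, d)
      i1 <- max(1, 1 - off[1]); i2 <- min(d[1], d[1] - off[1])
      j1 <- max(1, 1 - off[2]); j2 <- min(d[2], d[2] - off[2])
      k1 <- max(1, 1 - off[3]); k2 <- min(d[3], d[3] - off[3])
      nb[i1:i2, j1:j2, k1:k2] <-
        mask[(i1 + off[1]):(i2 + off[1]),
             (j1 + off[2]):(j2 + off[2]),
             (k1 + off[3]):(k2 + off[3])]
      area <- area + sum(mask & !nb) * face[ax]
    }
  }
  area
}
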