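#' Resample a volume and mask to isotropic voxels
#'
#' Trilinear interpolation of the intensity volume onto an isotropic grid
#' (1 mm by default), with the mask interpolated the same way and
#' re-binarized at 0.5. Voxel centers sit at `(i - 0.5) * spacing` so the
#' physical extent is preserved; output dimensions are
#' `round(dim * spacing / target)` (at least 1).
#'
#' @param volume 3D numeric array.
#' @param mask logical/0-1 array, same dimensions.
#' @param spacing input voxel spacing in mm (length 3, all > 0).
#' @param target target isotropic spacing in mm.
#' @return list with `volume`, `mask` (logical) and `spacing = c(t, t, t)`.
#' @export
resample_isotropic <- function(volume, mask, spacing, target = 1.0) {
  stopifnot(all(spacing > 0), target > 0,
            all(dim(volume) == dim(mask)))
  d <- dim(volume)
  if (all(abs(spacing - target) < 1e-12))
    return(list(volume = volume, mask = mask > 0,
                spacing = rep(target, 3)))
  dout <- pmax(1L, as.integer(round(d * spacing / target)))
  # continuous input index of each output voxel center
  ci <- lapply(1:3, function(ax)
    ((seq_len(dout[ax]) - 0.5) * target) / spacing[ax] + 0.5)
  vol_out <- .trilinear(volume, ci, dout)
  mask_out <- .trilinear((mask > 0) * 1, ci, dout) >= 0.5
  if (!any(mask_out))
    stop("mask vanished during resampling", call. = FALSE)
  list(volume = vol_out, mask = mask_out, spacing = rep(target, 3))
}

# Separable trilinear interpolation at the grid defined by continuous
# indices ci (one vector per axis), edge-clamped.
.trilinear <- function(arr, ci, dout) {
  d <- dim(arr)
  lo <- list(); fr <- list()
  for (ax in 1:3) {
    x <- pmin(pmax(ci[[ax]], 1), d[ax])
    l <- pmin(floor(x), d[ax] - ifelse(d[ax] > 1, 1, 0))
    l <- pmax(l, 1)
    lo[[ax]] <- as.integer(l)
    fr[[ax]] <- if (d[ax] > 1) x - l else rep(0, length(x))
  }
  hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1L, d[ax]))
  out <- array(0, dout)
  for (bi in 0:1) for (bj in 0:1) for (bk in 0:1) {
    ii <- if (bi == 0) lo[[1]] else hi[[1]]
    jj <- if (bj == 0) lo[[2]] else hi[[2]]
    kk <- if (bk == 0) lo[[3]] else hi[[3]]
    wi <- if (bi == 0) 1 - fr[[1]] else fr[[1]]
    wj <- if (bj == 0) 1 - fr[[2]] else fr[[2]]
    wk <- if (bk == 0) 1 - fr[[3]] else fr[[3]]
    w <- outer(outer(wi, wj), wk)
    out <- out + w * arr[cbind(rep(ii, times = dout[2] * dout[3]),
                               rep(rep(jj, each = dout[1]),
                                   times = dout[3]),
                               rep(kk, each = dout[1] * dout[2]))]
  }
  out
}
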