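#' Discretization specification for gray-level binning
#'
#' Absolute-bound discretization of Hounsfield units into equal-width bins,
#' as used for CT texture analysis: a fixed intensity range is divided into
#' `n_bins` bins and out-of-range values clip into the edge bins. The
#' defaults follow the extraction configuration used throughout the package:
#' 128 gray levels over \[-400, 400\] HU for co-occurrence, run-length and
#' neighborhood-difference features, and 32 levels over the same range for
#' zone-length features (per IBSI recommendations for that family).
#'
#' @param n_bins number of gray levels (>= 2).
#' @param lo,hi lower/upper bound of the absolute intensity range (HU).
#' @return an object of class `discretization_spec`.
#' @export
discretization_spec <- function(n_bins = 128, lo = -400, hi = 400) {
  stopifnot(n_bins >= 2, hi > lo)
  structure(list(n_bins = as.integer(n_bins), lo = lo, hi = hi),
            class = "discretization_spec")
}

#' Discretize a masked volume into gray-level labels
#'
#' Maps intensity `v` to bin `floor((v - lo) / ((hi - lo) / n_bins)) + 1`,
#' clipped to `[1, n_bins]`; the upper bound `v = hi` maps into bin
#' `n_bins`. Voxels outside the mask become `NA`.
#'
#' @param volume 3D numeric array of intensities (HU).
#' @param mask logical/0-1 array of the same dimensions.
#' @param spec a [discretization_spec()].
#' @return integer array of gray-level labels (`NA` outside the mask).
#' @export
discretize <- function(volume, mask, spec = discretization_spec()) {
  stopifnot(inherits(spec, "discretization_spec"),
            all(dim(volume) == dim(mask)))
  w <- (spec$hi - spec$lo) / spec$n_bins
  lab <- floor((volume - spec$lo) / w) + 1
  lab <- pmin(pmax(lab, 1), spec$n_bins)
  lab[!(mask > 0)] <- NA
  storage.mode(lab) <- "integer"
  array(lab, dim = dim(volume))
}

# The 13 unique 3D directions (26-neighborhood up to sign).
.directions13 <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(1, -1, -1)
  )
}

# For one offset, the aligned label pairs (A[i], B[i]) = (L[v], L[v + off]).
# Returns a list of two equal-length vectors (may contain NA).
.shift_pairs <- function(L, off) {
  d <- dim(L)
  i1 <- max(1, 1 - off[1]); i2 <- min(d[1], d[1] - off[1])
  j1 <- max(1, 1 - off[2]); j2 <- min(d[2], d[2] - off[2])
  k1 <- max(1, 1 - off[3]); k2 <- min(d[3], d[3] - off[3])
  if (i1 > i2 || j1 > j2 || k1 > k2)
    return(list(a = integer(0), b = integer(0), ia = integer(0),
                ib = integer(0)))
  # linear indices of the source and target blocks
  ii <- i1:i2; jj <- j1:j2; kk <- k1:k2
  ia <- as.vector(outer(outer(ii, (jj - 1) * d[1], "+"),
                        (kk - 1) * d[1] * d[2], "+"))
  shift <- off[1] + off[2] * d[1] + off[3] * d[1] * d[2]
  ib <- ia + shift
  list(a = L[ia], b = L[ib], ia = ia, ib = ib)
}
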