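#' Neighborhood gray-level difference matrix (NGLDM) features
#'
#' For each in-mask voxel with at least one in-mask 26-neighbor, the
#' absolute difference between its gray level and the mean gray level of its
#' in-mask neighbors is accumulated per gray level: `s_i = sum |i - Abar|`
#' over voxels of level `i`, with occupancy probabilities `p_i = n_i / N`
#' over the `N` contributing voxels.
#'
#' Features (Amadasun-style definitions):
#' Coarseness `1 / sum p_i s_i` (capped at `coarseness_cap` when the
#' denominator vanishes, e.g. a constant region); Contrast
#' `(sum_{i != j} p_i p_j (i-j)^2 / (Ngp (Ngp - 1))) * (sum s_i / N)` with
#' `Ngp` the number of occupied levels (0 when `Ngp < 2`); Busyness
#' `sum p_i s_i / sum_{i != j} |i p_i - j p_j|` over occupied levels
#' (0 when its numerator is 0, `NA` if only the denominator vanishes).
#'
#' @inheritParams glcm_features
#' @param coarseness_cap cap applied when the Coarseness denominator is 0.
#' @return named numeric vector: Coarseness, Busyness, Contrast_NGLDM.
#' @export
ngldm_features <- function(labels, coarseness_cap = 1e6) {
  st <- ngldm_table(labels)
  .ngldm_features_from_table(st$s, st$n, coarseness_cap)
}

#' Per-gray-level NGLDM difference sums
#' @inheritParams glcm_features
#' @return list with `s` (summed absolute differences per gray level) and
#'   `n` (contributing voxel counts per gray level).
#' @export
ngldm_table <- function(labels) {
  if (!any(!is.na(labels))) stop("empty mask", call. = FALSE)
  d <- dim(labels)
  ng <- max(labels, na.rm = TRUE)
  num <- array(0, d)   # sum of in-mask neighbor labels
  cnt <- array(0L, d)  # number of in-mask neighbors
  dirs <- .directions13()
  for (r in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      pr <- .shift_pairs(labels, sgn * dirs[r, ])
      keep <- !is.na(pr$a) & !is.na(pr$b)
      if (!any(keep)) next
      ia <- pr$ia[keep]
      num[ia] <- num[ia] + pr$b[keep]
      cnt[ia] <- cnt[ia] + 1L
    }
  }
  use <- !is.na(labels) & cnt > 0
  if (!any(use))
    stop("no voxel has an in-mask neighbor", call. = FALSE)
  diffs <- abs(labels[use] - num[use] / cnt[use])
  lv <- labels[use]
  list(s = vapply(seq_len(ng), function(i) sum(diffs[lv == i]), numeric(1)),
       n = tabulate(lv, nbins = ng))
}

.ngldm_features_from_table <- function(s, n, coarseness_cap = 1e6) {
  N <- sum(n)
  p <- n / N
  occ <- which(n > 0)
  den <- sum(p * s)
  coarse <- if (den > 1e-12) 1 / den else coarseness_cap
  coarse <- min(coarse, coarseness_cap)
  ngp <- length(occ)
  if (ngp >= 2) {
    ii <- matrix(occ, ngp, ngp); jj <- t(ii)
    pp <- outer(p[occ], p[occ])
    contrast <- sum(pp * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(s) / N
    bden <- sum(abs(outer(occ * p[occ], occ * p[occ], "-")))
    busy <- if (bden > 1e-12) den / bden else if (den <= 1e-12) 0 else NA_real_
  } else {
    contrast <- 0
    busy <- 0
  }
  c(Coarseness = coarse, Busyness = busy, Contrast_NGLDM = contrast)
}
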