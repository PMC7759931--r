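#' Gray-level run-length matrix (GLRLM) features
#'
#' Runs of consecutive equal gray levels along each of the 13 unique 3D
#' directions, pooled into a single run-length matrix `r(i, l)` (gray level
#' `i`, run length `l`) before feature computation. Out-of-mask voxels break
#' runs. With `Nr = sum r` and `Nv` the number of in-mask voxels:
#' SRE `sum r/l^2 / Nr`, LRE `sum r l^2 / Nr`, LGRE `sum r/i^2 / Nr`,
#' HGRE `sum r i^2 / Nr`, the four joint emphases (SRLGE, SRHGE, LRLGE,
#' LRHGE, e.g. LRHGE `= sum r l^2 i^2 / Nr`), GLNUr `sum_i (sum_l r)^2 /
#' Nr`, RLNU `sum_l (sum_i r)^2 / Nr`, and RP `= Nr / (D * Nv)` with `D`
#' the number of directions pooled.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of the eleven GLRLM features.
#' @export
glrlm_features <- function(labels, directions = .directions13()) {
  R <- glrlm_matrix(labels, directions)
  nv <- sum(!is.na(labels))
  .glrlm_features_from_matrix(R, nv, nrow(directions))
}

#' Pooled run-length matrix
#' @inheritParams glcm_features
#' @return matrix with gray levels in rows and run lengths in columns.
#' @export
glrlm_matrix <- function(labels, directions = .directions13()) {
  if (!any(!is.na(labels))) stop("empty mask", call. = FALSE)
  d <- dim(labels)
  ng <- max(labels, na.rm = TRUE)
  maxlen <- max(d)
  R <- matrix(0, ng, maxlen)
  ci <- slice.index(labels, 1)
  cj <- slice.index(labels, 2)
  ck <- slice.index(labels, 3)
  for (r in seq_len(nrow(directions))) {
    off <- directions[r, ]
    # steps backwards to the line start along -off, per axis
    m <- rep(Inf, length(labels))
    for (ax in 1:3) {
      cc <- switch(ax, ci, cj, ck)
      if (off[ax] > 0) m <- pmin(m, cc - 1)
      else if (off[ax] < 0) m <- pmin(m, d[ax] - cc)
    }
    si <- ci - m * off[1]; sj <- cj - m * off[2]; sk <- ck - m * off[3]
    lineid <- si + d[1] * (sj - 1) + d[1] * d[2] * (sk - 1)
    ord <- order(lineid, m)
    lab <- as.vector(labels)[ord]
    lid <- lineid[ord]
    n <- length(lab)
    labne <- lab[-1] != lab[-n]
    labne[is.na(labne)] <- TRUE
    brk <- c(TRUE, lid[-1] != lid[-n] | labne)
    runid <- cumsum(brk)
    lens <- tabulate(runid)
    rlab <- lab[brk]
    keep <- !is.na(rlab)
    if (!any(keep)) next
    inc <- tabulate((rlab[keep] - 1L) * maxlen + lens[keep],
                    nbins = ng * maxlen)
    R <- R + matrix(inc, ng, maxlen, byrow = TRUE)
  }
  R
}

.glrlm_features_from_matrix <- function(R, n_voxels, n_directions) {
  nr <- sum(R)
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  l <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
  c(SRE = sum(R / l^2) / nr,
    LRE = sum(R * l^2) / nr,
    LGRE = sum(R / i^2) / nr,
    HGRE = sum(R * i^2) / nr,
    SRLGE = sum(R / (i^2 * l^2)) / nr,
    SRHGE = sum(R * i^2 / l^2) / nr,
    LRLGE = sum(R * l^2 / i^2) / nr,
    LRHGE = sum(R * i^2 * l^2) / nr,
    GLNUr = sum(rowSums(R)^2) / nr,
    RLNU = sum(colSums(R)^2) / nr,
    RP = nr / (n_directions * n_voxels))
}
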