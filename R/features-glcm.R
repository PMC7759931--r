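#' Gray-level co-occurrence matrix (GLCM) features
#'
#' Co-occurrence counts at distance 1 over the 13 unique 3D directions (or a
#' supplied subset), symmetrized and pooled into a single normalized matrix
#' before feature computation. Only voxel pairs with both ends inside the
#' mask contribute.
#'
#' Features (standard definitions on the pooled normalized matrix `p(i,j)`
#' with gray levels `i, j`):
#' Homogeneity `sum p/(1+|i-j|)`, Energy `sum p^2`, Contrast
#' `sum (i-j)^2 p`, Dissimilarity `sum |i-j| p`, Entropy `-sum p log p`
#' (natural log), Correlation `sum (i-mu_i)(j-mu_j) p / (sd_i sd_j)`.
#' With a single occupied gray level the Correlation is undefined and `NA`
#' is returned for it.
#'
#' @param labels integer gray-level array with `NA` outside the mask, as
#'   produced by [discretize()].
#' @param directions matrix of integer offsets (rows); defaults to the 13
#'   unique 3D directions.
#' @return named numeric vector of the six GLCM features.
#' @export
glcm_features <- function(labels, directions = .directions13()) {
  P <- glcm_matrix(labels, directions)
  .glcm_features_from_matrix(P)
}

#' Pooled symmetric co-occurrence matrix
#' @inheritParams glcm_features
#' @return square matrix of co-occurrence probabilities (sums to 1).
#' @export
glcm_matrix <- function(labels, directions = .directions13()) {
  ng <- max(labels, na.rm = TRUE)
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(directions))) {
    pr <- .shift_pairs(labels, directions[r, ])
    keep <- !is.na(pr$a) & !is.na(pr$b)
    if (!any(keep)) next
    a <- pr$a[keep]; b <- pr$b[keep]
    tab <- tabulate((a - 1L) * ng + b, nbins = ng * ng) +
      tabulate((b - 1L) * ng + a, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  if (sum(counts) == 0)
    stop("no in-mask voxel pairs for co-occurrence", call. = FALSE)
  counts / sum(counts)
}

.glcm_features_from_matrix <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_ <- rowSums(P)
  mu_i <- sum(seq_len(ng) * pi_)
  sd_i <- sqrt(sum((seq_len(ng) - mu_i)^2 * pi_))
  nz <- P > 0
  corr <- if (sd_i > 1e-12) {
    sum((i - mu_i) * (j - mu_i) * P) / (sd_i * sd_i)
  } else NA_real_
  c(Homogeneity = sum(P / (1 + abs(i - j))),
    Energy = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    Entropy = -sum(P[nz] * log(P[nz])),
    Dissimilarity = sum(abs(i - j) * P))
}
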