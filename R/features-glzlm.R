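#' Gray-level zone-length matrix (GLZLM) features
#'
#' Zones are 26-connected components of equal gray level within the mask,
#' collected into a zone matrix `z(i, s)` (gray level `i`, zone size `s`).
#' By convention this family is computed on a coarser discretization (32
#' levels by default in [extract_all()]). With `Nz = sum z` zones and `Nv`
#' in-mask voxels: SZE `sum z/s^2 / Nz`, LZE `sum z s^2 / Nz`, the
#' gray-level emphases and joint emphases analogous to the run-length
#' family, GLNUz `sum_i (sum_s z)^2 / Nz`, ZLNU `sum_s (sum_i z)^2 / Nz`,
#' and ZP `= Nz / Nv`.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of the eleven GLZLM features.
#' @export
glzlm_features <- function(labels) {
  zm <- glzlm_matrix(labels)
  nv <- sum(!is.na(labels))
  .glzlm_features_from_matrix(zm, nv)
}

#' Zone-length matrix via 26-connected components
#' @inheritParams glcm_features
#' @return matrix with gray levels in rows and zone sizes in columns.
#' @export
glzlm_matrix <- function(labels) {
  vox <- which(!is.na(labels))
  if (length(vox) == 0) stop("empty mask", call. = FALSE)
  ng <- max(labels, na.rm = TRUE)
  # vertex ids: position of each in-mask voxel in `vox`
  vid <- integer(length(labels))
  vid[vox] <- seq_along(vox)
  edges <- vector("list", 13)
  dirs <- .directions13()
  for (r in seq_len(nrow(dirs))) {
    pr <- .shift_pairs(labels, dirs[r, ])
    keep <- !is.na(pr$a) & !is.na(pr$b) & pr$a == pr$b
    if (!any(keep)) next
    edges[[r]] <- rbind(vid[pr$ia[keep]], vid[pr$ib[keep]])
  }
  em <- do.call(cbind, edges[!vapply(edges, is.null, logical(1))])
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(em) && ncol(em) > 0)
    g <- igraph::add_edges(g, as.vector(em))
  comp <- igraph::components(g)
  sizes <- comp$csize
  # gray level of each component = label of any member voxel
  first_member <- match(seq_len(comp$no), comp$membership)
  glev <- labels[vox[first_member]]
  maxs <- max(sizes)
  Z <- matrix(0, ng, maxs)
  inc <- tabulate((glev - 1L) * maxs + sizes, nbins = ng * maxs)
  Z + matrix(inc, ng, maxs, byrow = TRUE)
}

.glzlm_features_from_matrix <- function(Z, n_voxels) {
  nz <- sum(Z)
  i <- matrix(seq_len(nrow(Z)), nrow(Z), ncol(Z))
  s <- t(matrix(seq_len(ncol(Z)), ncol(Z), nrow(Z)))
  c(SZE = sum(Z / s^2) / nz,
    LZE = sum(Z * s^2) / nz,
    LGZE = sum(Z / i^2) / nz,
    HGZE = sum(Z * i^2) / nz,
    SZLGE = sum(Z / (i^2 * s^2)) / nz,
    SZHGE = sum(Z * i^2 / s^2) / nz,
    LZLGE = sum(Z * s^2 / i^2) / nz,
    LZHGE = sum(Z * i^2 * s^2) / nz,
    GLNUz = sum(rowSums(Z)^2) / nz,
    ZLNU = sum(colSums(Z)^2) / nz,
    ZP = nz / n_voxels)
}
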