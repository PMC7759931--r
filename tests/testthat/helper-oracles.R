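# Brute-force enumeration oracles for the texture families. These are
# deliberately written as plain per-voxel loops, independent of the
# package's vectorized matrix construction, and compute features by direct
# summation over matrix entries.

oracle_offsets26 <- function() {
  out <- list()
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    if (a == 0 && b == 0 && c == 0) next
    out[[length(out) + 1]] <- c(a, b, c)
  }
  out
}

oracle_offsets13 <- function() {
  offs <- oracle_offsets26()
  keep <- list()
  for (o in offs) {
    if (o[1] > 0 || (o[1] == 0 && o[2] > 0) ||
        (o[1] == 0 && o[2] == 0 && o[3] > 0)) keep[[length(keep) + 1]] <- o
  }
  keep
}

.in_grid <- function(i, j, k, d) {
  i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3]
}

# ---- GLCM ----
oracle_glcm_matrix <- function(lab) {
  d <- dim(lab)
  ng <- max(lab, na.rm = TRUE)
  M <- matrix(0, ng, ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lab[i, j, k])) next
    for (o in oracle_offsets26()) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (!.in_grid(ii, jj, kk, d)) next
      if (is.na(lab[ii, jj, kk])) next
      M[lab[i, j, k], lab[ii, jj, kk]] <- M[lab[i, j, k], lab[ii, jj, kk]] + 1
    }
  }
  M / sum(M)
}

oracle_glcm_features <- function(lab) {
  P <- oracle_glcm_matrix(lab)
  ng <- nrow(P)
  hom <- ene <- con <- dis <- ent <- 0
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * P[i, j]
  s2 <- 0
  for (i in 1:ng) for (j in 1:ng) s2 <- s2 + (i - mu)^2 * P[i, j]
  num <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    hom <- hom + p / (1 + abs(i - j))
    ene <- ene + p^2
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    if (p > 0) ent <- ent - p * log(p)
    num <- num + (i - mu) * (j - mu) * p
  }
  corr <- if (s2 > 1e-12) num / s2 else NA_real_
  c(Homogeneity = hom, Energy = ene, Contrast = con, Correlation = corr,
    Entropy = ent, Dissimilarity = dis)
}

# ---- GLRLM ----
oracle_glrlm_matrix <- function(lab, dirs = oracle_offsets13()) {
  d <- dim(lab)
  ng <- max(lab, na.rm = TRUE)
  R <- matrix(0, ng, max(d))
  for (o in dirs) {
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (is.na(lab[i, j, k])) next
      pi_ <- i - o[1]; pj <- j - o[2]; pk <- k - o[3]
      if (.in_grid(pi_, pj, pk, d) && !is.na(lab[pi_, pj, pk]) &&
          lab[pi_, pj, pk] == lab[i, j, k]) next  # not a run start
      len <- 1
      ci <- i + o[1]; cj <- j + o[2]; ck <- k + o[3]
      while (.in_grid(ci, cj, ck, d) && !is.na(lab[ci, cj, ck]) &&
             lab[ci, cj, ck] == lab[i, j, k]) {
        len <- len + 1
        ci <- ci + o[1]; cj <- cj + o[2]; ck <- ck + o[3]
      }
      R[lab[i, j, k], len] <- R[lab[i, j, k], len] + 1
    }
  }
  R
}

oracle_glrlm_features <- function(lab, dirs = oracle_offsets13()) {
  R <- oracle_glrlm_matrix(lab, dirs)
  nr <- sum(R)
  nv <- sum(!is.na(lab))
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  for (i in 1:nrow(R)) for (l in 1:ncol(R)) {
    r <- R[i, l]
    if (r == 0) next
    sre <- sre + r / l^2; lre <- lre + r * l^2
    lgre <- lgre + r / i^2; hgre <- hgre + r * i^2
    srlge <- srlge + r / (i^2 * l^2); srhge <- srhge + r * i^2 / l^2
    lrlge <- lrlge + r * l^2 / i^2; lrhge <- lrhge + r * i^2 * l^2
  }
  glnu <- sum(sapply(1:nrow(R), function(i) sum(R[i, ])^2))
  rlnu <- sum(sapply(1:ncol(R), function(l) sum(R[, l])^2))
  c(SRE = sre / nr, LRE = lre / nr, LGRE = lgre / nr, HGRE = hgre / nr,
    SRLGE = srlge / nr, SRHGE = srhge / nr, LRLGE = lrlge / nr,
    LRHGE = lrhge / nr, GLNUr = glnu / nr, RLNU = rlnu / nr,
    RP = nr / (length(dirs) * nv))
}

# ---- GLZLM ----
oracle_zones <- function(lab) {
  d <- dim(lab)
  visited <- array(FALSE, d)
  zones <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lab[i, j, k]) || visited[i, j, k]) next
    lev <- lab[i, j, k]
    queue <- list(c(i, j, k))
    visited[i, j, k] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (o in oracle_offsets26()) {
        w <- v + o
        if (!.in_grid(w[1], w[2], w[3], d)) next
        if (visited[w[1], w[2], w[3]]) next
        if (is.na(lab[w[1], w[2], w[3]])) next
        if (lab[w[1], w[2], w[3]] != lev) next
        visited[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1]] <- w
      }
    }
    zones[[length(zones) + 1]] <- c(level = lev, size = size)
  }
  zones
}

oracle_glzlm_features <- function(lab) {
  zs <- oracle_zones(lab)
  nz <- length(zs)
  nv <- sum(!is.na(lab))
  sze <- lze <- lgze <- hgze <- szlge <- szhge <- lzlge <- lzhge <- 0
  for (z in zs) {
    i <- z["level"]; s <- z["size"]
    sze <- sze + 1 / s^2; lze <- lze + s^2
    lgze <- lgze + 1 / i^2; hgze <- hgze + i^2
    szlge <- szlge + 1 / (i^2 * s^2); szhge <- szhge + i^2 / s^2
    lzlge <- lzlge + s^2 / i^2; lzhge <- lzhge + i^2 * s^2
  }
  levs <- sapply(zs, `[`, "level")
  sizes <- sapply(zs, `[`, "size")
  glnu <- sum(sapply(unique(levs), function(l) sum(levs == l)^2))
  zlnu <- sum(sapply(unique(sizes), function(s) sum(sizes == s)^2))
  unname_vec <- function(x) as.numeric(x)
  c(SZE = unname_vec(sze / nz), LZE = unname_vec(lze / nz),
    LGZE = unname_vec(lgze / nz), HGZE = unname_vec(hgze / nz),
    SZLGE = unname_vec(szlge / nz), SZHGE = unname_vec(szhge / nz),
    LZLGE = unname_vec(lzlge / nz), LZHGE = unname_vec(lzhge / nz),
    GLNUz = glnu / nz, ZLNU = zlnu / nz, ZP = nz / nv)
}

# ---- NGLDM ----
oracle_ngldm_features <- function(lab, cap = 1e6) {
  d <- dim(lab)
  ng <- max(lab, na.rm = TRUE)
  s <- numeric(ng); n <- numeric(ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lab[i, j, k])) next
    tot <- 0; cnt <- 0
    for (o in oracle_offsets26()) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (!.in_grid(ii, jj, kk, d)) next
      if (is.na(lab[ii, jj, kk])) next
      tot <- tot + lab[ii, jj, kk]; cnt <- cnt + 1
    }
    if (cnt == 0) next
    lev <- lab[i, j, k]
    s[lev] <- s[lev] + abs(lev - tot / cnt)
    n[lev] <- n[lev] + 1
  }
  N <- sum(n)
  p <- n / N
  den <- 0
  for (i in 1:ng) den <- den + p[i] * s[i]
  coarse <- if (den > 1e-12) min(1 / den, cap) else cap
  occ <- which(n > 0)
  if (length(occ) >= 2) {
    con <- 0
    for (i in occ) for (j in occ) con <- con + p[i] * p[j] * (i - j)^2
    con <- con / (length(occ) * (length(occ) - 1)) * sum(s) / N
    bden <- 0
    for (i in occ) for (j in occ) bden <- bden + abs(i * p[i] - j * p[j])
    busy <- if (bden > 1e-12) den / bden else if (den <= 1e-12) 0
            else NA_real_
  } else {
    con <- 0; busy <- 0
  }
  c(Coarseness = coarse, Busyness = busy, Contrast_NGLDM = con)
}

# Random labelled test volume: dims in [3, maxdim], levels 1..nlev, a
# random subset of voxels masked out.
random_label_volume <- function(maxdim = 6, nlev = 4, p_mask = 0.85) {
  d <- sample(3:maxdim, 3, replace = TRUE)
  lab <- array(sample.int(nlev, prod(d), replace = TRUE), d)
  keep <- array(runif(prod(d)) < p_mask, d)
  if (!any(keep)) keep[1, 1, 1] <- TRUE
  lab[!keep] <- NA
  storage.mode(lab) <- "integer"
  lab
}
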