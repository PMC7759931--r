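#' Flag multivariate outliers via a robust covariance estimate
#'
#' Deterministic reweighted estimator of multivariate location and scatter
#' in the spirit of robust S/MCD estimators: starting from coordinatewise
#' medians and MADs, robust Mahalanobis distances are computed, the scatter
#' re-estimated from the rows below the chi-squared 0.975 cutoff (with a
#' consistency correction), and the procedure iterated to a fixed point.
#' Rows whose final robust distance exceeds the `chi2(p, 0.975)` quantile
#' are flagged. When `n <= p` (or the scatter degenerates) it is shrunk
#' toward its diagonal with a logged intensity.
#'
#' @param data numeric matrix/data.frame (rows = observations; typically
#'   the response plus the transformed features).
#' @param quantile chi-squared cutoff probability.
#' @param max_iter iteration cap.
#' @return list with `outlier` (logical per row), `distance` (robust
#'   Mahalanobis distances), `center`, `scatter`, `shrinkage` (0 when no
#'   regularization was needed).
#' @export
detect_outliers_robust_cov <- function(data, quantile = 0.975,
                                       max_iter = 50) {
  X <- as.matrix(data)
  if (any(!is.finite(X))) stop("data must be complete and finite",
                               call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  cutoff <- qchisq(quantile, df = p)
  ctr <- apply(X, 2, median)
  scl <- apply(X, 2, mad)
  scl[scl == 0] <- 1e-8
  S <- diag(scl^2, p)
  shrink_used <- 0
  regularize <- function(S) {
    lam <- 0
    Sr <- S
    repeat {
      ev <- tryCatch(min(eigen(Sr, symmetric = TRUE,
                               only.values = TRUE)$values),
                     error = function(e) -1)
      if (is.finite(ev) && ev > 1e-10 * max(diag(Sr))) break
      lam <- if (lam == 0) 0.1 else min(lam * 2, 1)
      Sr <- (1 - lam) * S + lam * diag(diag(S), p)
      if (lam >= 1) break
    }
    list(S = Sr, lambda = lam)
  }
  d2 <- rep(Inf, n)
  for (it in seq_len(max_iter)) {
    rg <- regularize(S)
    shrink_used <- max(shrink_used, rg$lambda)
    d2_new <- mahalanobis(X, ctr, rg$S)
    keep <- d2_new <= cutoff
    if (sum(keep) < p + 1) {
      keep <- rank(d2_new, ties.method = "first") <=
        max(p + 1, ceiling(n / 2))
    }
    ctr_new <- colMeans(X[keep, , drop = FALSE])
    S_new <- cov(X[keep, , drop = FALSE])
    # consistency correction for the truncation
    cc <- quantile / pchisq(cutoff, df = p + 2)
    S_new <- S_new * cc
    if (max(abs(d2_new - d2)) < 1e-10) {
      d2 <- d2_new
      break
    }
    d2 <- d2_new
    ctr <- ctr_new
    S <- S_new
  }
  rg <- regularize(S)
  if (all(!is.finite(d2))) stop("degenerate scatter", call. = FALSE)
  list(outlier = d2 > cutoff, distance = sqrt(d2), center = ctr,
       scatter = rg$S, shrinkage = max(shrink_used, rg$lambda))
}
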