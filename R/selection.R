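## Global predictor selection for clustered data.
##
## Both procedures treat the spiked random predictors as negative controls
## governing where to stop: the LASSO keeps the sparsest part of the path
## free of random predictors, the stepwise search halts when a random
## predictor would be the best addition.

# GLS whitening of a random-intercept model at variance ratio theta:
# per patient block, (I + theta J)^(-1/2) = I - c J with
# c = (1 - 1/sqrt(1 + theta m)) / m for a group of size m.
.whiten <- function(M, gint, theta) {
  M <- as.matrix(M)
  gm <- rowsum.default(M, gint, reorder = FALSE)
  sizes <- as.vector(rowsum.default(rep(1, nrow(M)), gint,
                                    reorder = FALSE))
  cc <- (1 - 1 / sqrt(1 + theta * sizes)) / sizes
  idx <- match(gint, unique(gint))
  M - (cc[idx]) * gm[idx, , drop = FALSE]
}

#' LASSO path for the random-intercept model
#'
#' L1-penalized fixed effects in the random-intercept model, computed by
#' exact GLS whitening: at the current variance components the penalized
#' problem is an ordinary lasso on the whitened response and design, solved
#' with glmnet; variance components are re-estimated from the active set
#' and the whitening iterated to a fixed point per lambda. Predictors must
#' be standardized (z-scored) beforehand, as required for comparable
#' penalization; the intercept is carried as an unpenalized whitened
#' column.
#'
#' @param y response vector.
#' @param X_std matrix of z-scored predictors (each column: |mean| < 1e-6,
#'   |sd - 1| < 1e-3).
#' @param groups patient ids.
#' @param lambda optional decreasing lambda grid; defaults to 100
#'   log-spaced values from the smallest empty-active-set lambda down by a
#'   factor 1000.
#' @param n_lambda,lambda_min_ratio grid size and lower ratio when
#'   `lambda` is NULL.
#' @param max_outer variance-component re-estimation sweeps.
#' @return object of class `lasso_mlm_path`: list with `lambda`,
#'   `active` (list of active column names per lambda), `beta` (matrix of
#'   penalized coefficients), `theta` (variance ratio per lambda).
#' @export
lasso_mlm_path <- function(y, X_std, groups, lambda = NULL,
                           n_lambda = 100, lambda_min_ratio = 1e-3,
                           max_outer = 5) {
  X_std <- as.matrix(X_std)
  mns <- colMeans(X_std)
  sds <- apply(X_std, 2, sd)
  if (any(abs(mns) > 1e-6) || any(abs(sds - 1) > 1e-3))
    stop("predictors must be standardized (z-scored) for the penalized fit",
         call. = FALSE)
  if (is.null(colnames(X_std)))
    colnames(X_std) <- paste0("x", seq_len(ncol(X_std)))
  gint <- as.integer(factor(groups))
  ng <- max(gint)
  n <- length(y)

  # initial variance ratio from the intercept-only model
  fit0 <- .mlm_fit_fast(y, matrix(1, n, 1), gint, ng, reml = TRUE)
  theta0 <- fit0$sigma2_patient / fit0$sigma2_resid

  if (is.null(lambda)) {
    yw <- .whiten(y, gint, theta0)
    Xw <- .whiten(X_std, gint, theta0)
    ones_w <- .whiten(matrix(1, n, 1), gint, theta0)
    # residualize against the unpenalized intercept
    r <- yw - ones_w %*% (crossprod(ones_w, yw) / sum(ones_w^2))
    lmax <- max(abs(crossprod(Xw, r))) / n * 1.05
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = n_lambda))
  }

  p <- ncol(X_std)
  beta_path <- matrix(0, p, length(lambda),
                      dimnames = list(colnames(X_std), NULL))
  theta_path <- numeric(length(lambda))
  active <- vector("list", length(lambda))
  theta <- theta0
  for (li in seq_along(lambda)) {
    lam <- lambda[li]
    for (it in seq_len(max_outer)) {
      yw <- .whiten(y, gint, theta)
      Xw <- .whiten(cbind(`(Intercept)` = 1, X_std), gint, theta)
      fit <- glmnet::glmnet(Xw, yw, lambda = lam, standardize = FALSE,
                            intercept = FALSE,
                            penalty.factor = c(0, rep(1, p)))
      b <- as.vector(fit$beta)
      act <- which(abs(b[-1]) > 1e-10)
      # re-estimate variance components on the active design (skipped when
      # the active set approaches saturation and the GLS normal equations
      # degenerate)
      theta_new <- if (length(act) <= length(y) - ng - 2) {
        Xa <- cbind(1, X_std[, act, drop = FALSE])
        vc <- tryCatch(.mlm_fit_fast(y, Xa, gint, ng, reml = TRUE),
                       error = function(e) NULL)
        if (is.null(vc)) theta
        else vc$sigma2_patient / max(vc$sigma2_resid, 1e-12)
      } else theta
      if (abs(log((theta_new + 1e-8) / (theta + 1e-8))) < 1e-4) {
        theta <- theta_new
        break
      }
      theta <- theta_new
    }
    beta_path[, li] <- b[-1]
    theta_path[li] <- theta
    active[[li]] <- colnames(X_std)[abs(b[-1]) > 1e-10]
  }
  structure(list(lambda = lambda, active = active, beta = beta_path,
                 theta = theta_path),
            class = "lasso_mlm_path")
}

#' Select lambda by the random-predictor entry rule
#'
#' Negative-control calibration of the penalty: the selected lambda is the
#' smallest value whose active set contains no spiked random predictor;
#' the real predictors active there form the selected set. If some random
#' predictor is active along the whole path the selection is empty, with a
#' warning.
#'
#' @param path a [lasso_mlm_path()].
#' @param random_cols names of the random predictor columns in the path.
#' @return object of class `selection_result`: list with `selected`,
#'   `method = "lasso"`, `lambda`, `stopping` and the path.
#' @export
select_lambda_by_random_entry <- function(path, random_cols) {
  stopifnot(inherits(path, "lasso_mlm_path"))
  clean <- vapply(path$active,
                  function(a) !any(a %in% random_cols), logical(1))
  if (!any(clean)) {
    warning("a random predictor is active at every lambda; empty selection")
    return(structure(list(selected = character(0), method = "lasso",
                          lambda = NA_real_, stopping = "random-entered",
                          path = path), class = "selection_result"))
  }
  li <- max(which(clean))   # smallest clean lambda (grid is decreasing)
  sel <- setdiff(path$active[[li]], random_cols)
  structure(list(selected = sel, method = "lasso",
                 lambda = path$lambda[li],
                 stopping = if (li < length(path$lambda))
                   "random-entered" else "path-end",
                 path = path),
            class = "selection_result")
}

#' Stepwise selection maximizing marginal R-squared
#'
#' Greedy forward/backward search over the standardized predictors,
#' maximizing the marginal R-squared of the random-intercept model. The
#' iteration halts when the best candidate addition is a spiked random
#' predictor (negative-control stopping), when the best improvement falls
#' below `tol`, or at `max_steps`. After each addition, backward drops
#' remove predictors whose removal does not reduce R-squared by more than
#' `tol`. Ties are broken by feature name order.
#'
#' @param y response vector.
#' @param X_std matrix of z-scored predictors (real and random columns).
#' @param groups patient ids.
#' @param random_cols names of the random predictor columns.
#' @param method likelihood used for the fits ("ML" default).
#' @param tol minimum R-squared improvement.
#' @param max_steps cap on forward steps.
#' @return object of class `selection_result` with the step path.
#' @export
stepwise_r2 <- function(y, X_std, groups, random_cols, method = "ML",
                        tol = 1e-4, max_steps = 15) {
  X_std <- as.matrix(X_std)
  stopifnot(!is.null(colnames(X_std)))
  gint <- as.integer(factor(groups))
  ng <- max(gint)
  reml <- identical(method, "REML")
  r2_of <- function(sel) {
    Xs <- cbind(1, X_std[, sel, drop = FALSE])
    .mlm_fit_fast(y, Xs, gint, ng, reml = reml)$marginal_r2
  }
  selected <- character(0)
  r2_cur <- 0
  stopping <- "max-steps"
  steps <- list()
  for (s in seq_len(max_steps)) {
    cand <- setdiff(colnames(X_std), selected)
    if (!length(cand)) { stopping <- "no-candidates"; break }
    r2c <- vapply(cand, function(nm) r2_of(c(selected, nm)), numeric(1))
    ord <- order(-r2c, cand)
    best <- cand[ord[1]]
    best_r2 <- r2c[ord[1]]
    if (best_r2 - r2_cur < tol) { stopping <- "no-improvement"; break }
    if (best %in% random_cols) { stopping <- "random-entered"; break }
    selected <- c(selected, best)
    r2_cur <- best_r2
    steps[[length(steps) + 1]] <- list(action = "add", feature = best,
                                       r2 = r2_cur)
    # backward pass
    repeat {
      if (length(selected) < 2) break
      drop_r2 <- vapply(selected, function(nm)
        r2_of(setdiff(selected, nm)), numeric(1))
      ordd <- order(-drop_r2, selected)
      if (drop_r2[ordd[1]] >= r2_cur - tol) {
        victim <- selected[ordd[1]]
        selected <- setdiff(selected, victim)
        r2_cur <- drop_r2[ordd[1]]
        steps[[length(steps) + 1]] <- list(action = "drop",
                                           feature = victim, r2 = r2_cur)
      } else break
    }
  }
  structure(list(selected = selected, method = "stepwise",
                 stopping = stopping, r2 = r2_cur, steps = steps),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection (%s): %s\n", x$method,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "<empty>"))
  cat(sprintf("  stopping: %s\n", x$stopping))
  invisible(x)
}
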