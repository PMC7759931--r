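## Random-intercept linear mixed models.
##
## Model: y_i = x_i' beta + b_{g(i)} + e_i,  b_g ~ N(0, sigma2_patient),
## e_i ~ N(0, sigma2_resid / w_i) with optional prior weights w.
## The deviance is profiled: for a fixed variance ratio
## theta = sigma2_patient / sigma2_resid, beta and sigma2_resid have closed
## forms via blockwise Woodbury identities, leaving a 1-D optimization in
## log(theta). This keeps a single fit around a millisecond, which the
## Monte-Carlo stages (screening, null reference test) rely on.

# Per-fit sufficient statistics that do not depend on theta.
.mlm_prep <- function(y, X, groups, weights = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(groups) == n)
  if (is.null(weights)) weights <- rep(1, n)
  g <- as.integer(factor(groups))
  wX <- X * weights
  list(
    n = n, p = ncol(X), g = g, ngroups = max(g),
    XtWX = crossprod(X, wX),
    XtWy = crossprod(wX, y),
    ytWy = sum(weights * y * y),
    G = rowsum(wX, g),              # group sums of w*x
    h = as.vector(rowsum(weights * y, g)),
    s = as.vector(rowsum(weights, g)),  # group sums of w
    sumlogw = sum(log(weights)),
    X = X, y = y, weights = weights
  )
}

# Profiled quantities at a given theta >= 0. Returns beta, the GLS pieces,
# r' V*^-1 r and log det V* (V* = W^-1 + theta Z Z').
.mlm_profile <- function(prep, theta) {
  cg <- theta / (1 + theta * prep$s)
  XtVX <- prep$XtWX - crossprod(prep$G, cg * prep$G)
  XtVy <- prep$XtWy - crossprod(prep$G, cg * prep$h)
  ytVy <- prep$ytWy - sum(cg * prep$h^2)
  R <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(R)) stop("singular fixed-effect design", call. = FALSE)
  beta <- backsolve(R, forwardsolve(t(R), XtVy))
  rss <- max(ytVy - sum(beta * XtVy), 0)
  logdetV <- sum(log1p(theta * prep$s)) - prep$sumlogw
  list(beta = as.vector(beta), XtVX = XtVX, chol = R, rss = rss,
       logdetV = logdetV)
}

# -2 log (restricted) likelihood profiled over beta and sigma2_resid.
.mlm_deviance <- function(prep, theta, reml = TRUE) {
  pr <- .mlm_profile(prep, theta)
  n <- prep$n
  p <- prep$p
  if (reml) {
    s2 <- pr$rss / (n - p)
    (n - p) * log(2 * pi * s2) + pr$logdetV +
      2 * sum(log(diag(pr$chol))) + (n - p)
  } else {
    s2 <- pr$rss / n
    n * log(2 * pi * s2) + pr$logdetV + n
  }
}

#' Fit a random-intercept linear mixed model
#'
#' Gaussian linear mixed model with a single random intercept per group
#' (patient), the workhorse of the feature screens and association models.
#' Estimation maximizes the (restricted) likelihood by profiling the fixed
#' effects and residual variance out of the objective and optimizing the
#' patient-to-residual variance ratio on the log scale. Wald t statistics use
#' Satterthwaite-approximated denominator degrees of freedom.
#'
#' @param y numeric response vector (e.g. log maf).
#' @param X fixed-effect design matrix including the intercept column, full
#'   column rank.
#' @param groups grouping factor (patient identifiers), one per row.
#' @param method `"REML"` (default) or `"ML"`.
#' @param weights optional positive prior weights on observations; residual
#'   variance for row i is `sigma2_resid / weights[i]`.
#' @param ddf denominator degrees of freedom for the Wald t tests:
#'   `"satterthwaite"` (default) or `"residual"` (`n - p`; much cheaper,
#'   used inside simulation loops where only likelihoods matter).
#' @return An object of class `mlm_fit`: a list with `coefficients` (a
#'   data.frame with estimate, se, t, Satterthwaite df and p per fixed
#'   effect), `sigma2_patient`, `sigma2_resid`, `logLik`, `deviance`,
#'   `method`, `fitted` (marginal, fixed effects only), `ranef` (BLUPs),
#'   `marginal_r2`, and bookkeeping fields.
#' @examples
#' set.seed(1)
#' g <- rep(1:10, each = 4)
#' x <- rnorm(40)
#' y <- 1 + 0.5 * x + rnorm(10)[g] + rnorm(40, sd = 0.5)
#' fit <- fit_mlm(y, cbind(1, x), g)
#' fit$coefficients
#' @export
fit_mlm <- function(y, X, groups, method = c("REML", "ML"), weights = NULL,
                    ddf = c("satterthwaite", "residual")) {
  method <- match.arg(method)
  ddf <- match.arg(ddf)
  reml <- method == "REML"
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[
      seq_len(ncol(X))]
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient", call. = FALSE)
  if (length(unique(groups)) < 2 && nrow(X) > 1)
    warning("fewer than 2 groups; random intercept is not identifiable")
  prep <- .mlm_prep(y, X, groups, weights)

  core <- mlm_core_cpp(prep$XtWX, as.vector(prep$XtWy), prep$ytWy,
                       prep$G, prep$h, prep$s, prep$sumlogw,
                       prep$n, prep$p, reml)
  theta <- core$theta
  dev <- core$deviance
  pr <- list(beta = as.vector(core$beta), chol = core$cholXtVX,
             rss = core$rss)
  dfres <- if (reml) prep$n - prep$p else prep$n
  s2e <- pr$rss / dfres
  s2e <- max(s2e, 1e-12)
  s2p <- theta * s2e
  vcov_beta <- chol2inv(pr$chol) * s2e
  se <- sqrt(diag(vcov_beta))
  tval <- pr$beta / se
  df <- if (ddf == "satterthwaite") .satterthwaite_df(prep, theta, s2e, reml)
        else rep(prep$n - prep$p, prep$p)
  pval <- 2 * stats::pt(-abs(tval), df)

  fitted_fix <- as.vector(prep$X %*% pr$beta)
  # BLUPs of the patient intercepts
  resid_fix <- y - fitted_fix
  mres <- as.vector(rowsum(prep$weights * resid_fix, prep$g))
  blup <- theta * mres / (1 + theta * prep$s)
  coef_tab <- data.frame(
    term = colnames(X), estimate = pr$beta, se = se, t = tval,
    df = df, p = pval, row.names = NULL
  )
  vf <- if (prep$n > 1) stats::var(fitted_fix) * (prep$n - 1) / prep$n else 0
  structure(list(
    coefficients = coef_tab, vcov = vcov_beta,
    sigma2_patient = s2p, sigma2_resid = s2e, theta = theta,
    logLik = -dev / 2, deviance = dev, method = method,
    n = prep$n, ngroups = prep$ngroups, groups = groups,
    fitted = fitted_fix, residuals = y - fitted_fix - blup[prep$g],
    ranef = blup, weights = prep$weights,
    marginal_r2 = vf / (vf + s2p + s2e),
    X = prep$X, y = y, converged = TRUE
  ), class = "mlm_fit")
}

# Lean fitting path for simulation loops: integer group ids, no input
# checking, no Satterthwaite, minimal output. Returns what the screening and
# null-reference stages need (beta, t with residual df, logLik, variance
# components, marginal R2).
.mlm_fit_fast <- function(y, X, gint, ngroups, reml = TRUE) {
  n <- length(y)
  p <- ncol(X)
  G <- rowsum.default(X, gint, reorder = FALSE)
  h <- as.vector(rowsum.default(y, gint, reorder = FALSE))
  s <- as.vector(rowsum.default(rep(1, n), gint, reorder = FALSE))
  core <- mlm_core_cpp(crossprod(X), as.vector(crossprod(X, y)),
                       sum(y * y), G, h, s, 0, n, p, reml)
  dfres <- if (reml) n - p else n
  s2e <- max(core$rss / dfres, 1e-12)
  beta <- as.vector(core$beta)
  se <- sqrt(diag(chol2inv(core$cholXtVX)) * s2e)
  fitted <- as.vector(X %*% beta)
  vf <- if (n > 1) var(fitted) * (n - 1) / n else 0
  s2p <- core$theta * s2e
  list(beta = beta, se = se, t = beta / se, df = n - p,
       logLik = -core$deviance / 2, sigma2_patient = s2p,
       sigma2_resid = s2e,
       marginal_r2 = vf / (vf + s2p + s2e))
}

# Satterthwaite denominator df for each fixed effect.
# df_j = 2 v_j^2 / (grad' A^-1 grad) with v_j = Var(beta_j) as a function of
# the variance components (sigma2_patient, sigma2_resid) and A the observed
# REML information of those components (numeric derivatives; each evaluation
# is a cheap profiled solve). At the theta = 0 boundary the classical
# residual df applies.
.satterthwaite_df <- function(prep, theta, s2e, reml) {
  nres <- prep$n - prep$p
  if (theta < 1e-10) return(rep(nres, prep$p))
  vfun <- function(s2p, s2e) {
    th <- s2p / s2e
    pr <- .mlm_profile(prep, th)
    diag(chol2inv(pr$chol)) * s2e
  }
  devfun <- function(par) {
    # deviance as a function of (sigma2_patient, sigma2_resid), unprofiled
    # in sigma2_resid: rescale using the profiled pieces.
    s2p <- par[1]; s2 <- par[2]
    pr <- .mlm_profile(prep, s2p / s2)
    n <- prep$n; p <- prep$p
    if (reml)
      (n - p) * log(2 * pi * s2) + pr$logdetV +
        2 * sum(log(diag(pr$chol))) + pr$rss / s2
    else
      n * log(2 * pi * s2) + pr$logdetV + pr$rss / s2
  }
  s2p <- theta * s2e
  hp <- pmax(c(s2p, s2e) * 1e-4, 1e-10)
  par0 <- c(s2p, s2e)
  # gradient of v_j
  v0 <- vfun(s2p, s2e)
  g1 <- (vfun(s2p + hp[1], s2e) - vfun(max(s2p - hp[1], 0), s2e)) /
    (hp[1] + min(hp[1], s2p))
  g2 <- (vfun(s2p, s2e + hp[2]) - vfun(s2p, s2e - hp[2])) / (2 * hp[2])
  # observed information of -2 loglik / 2
  H <- matrix(0, 2, 2)
  f0 <- devfun(par0)
  for (a in 1:2) for (b in a:2) {
    ea <- eb <- c(0, 0); ea[a] <- hp[a]; eb[b] <- hp[b]
    H[a, b] <- H[b, a] <-
      (devfun(par0 + ea + eb) - devfun(par0 + ea - eb) -
         devfun(par0 - ea + eb) + devfun(par0 - ea - eb)) /
      (8 * hp[a] * hp[b])
  }
  Ainv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Ainv)) return(rep(nres, prep$p))
  df <- vapply(seq_len(prep$p), function(j) {
    gj <- c(g1[j], g2[j])
    den <- drop(t(gj) %*% Ainv %*% gj)
    if (!is.finite(den) || den <= 0) return(nres)
    2 * v0[j]^2 / den
  }, numeric(1))
  pmin(pmax(df, 1), nres)
}

#' Marginal R-squared of a mixed-model fit
#'
#' Proportion of response variance explained by the fixed effects alone:
#' `Var(X beta) / (Var(X beta) + sigma2_patient + sigma2_resid)`, with
#' `Var(X beta)` the (population) variance of the fixed-effect linear
#' predictor over the fitted rows. Component values may be supplied directly
#' instead of a fit.
#'
#' @param fit an `mlm_fit`, or `NULL` when explicit components are given.
#' @param var_fixed,sigma2_patient,sigma2_resid optional explicit components
#'   overriding those from `fit`.
#' @return scalar in \[0, 1\].
#' @export
marginal_r2 <- function(fit = NULL, var_fixed = NULL, sigma2_patient = NULL,
                        sigma2_resid = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "mlm_fit"))
    n <- fit$n
    if (is.null(var_fixed))
      var_fixed <- if (n > 1) stats::var(fit$fitted) * (n - 1) / n else 0
    if (is.null(sigma2_patient)) sigma2_patient <- fit$sigma2_patient
    if (is.null(sigma2_resid)) sigma2_resid <- fit$sigma2_resid
  }
  var_fixed / (var_fixed + sigma2_patient + sigma2_resid)
}

#' Likelihood-ratio test between nested ML fits
#'
#' Compares two maximum-likelihood fits of nested fixed-effect designs on the
#' same rows. REML fits are rejected because restricted likelihoods are not
#' comparable across fixed-effect designs.
#'
#' @param full,restricted `mlm_fit` objects fitted with `method = "ML"`.
#' @param df degrees of freedom of the test; defaults to the difference in
#'   the number of fixed-effect parameters.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt <- function(full, restricted, df = NULL) {
  stopifnot(inherits(full, "mlm_fit"), inherits(restricted, "mlm_fit"))
  if (full$method != "ML" || restricted$method != "ML")
    stop("LRT requires ML fits (REML likelihoods are not comparable across fixed designs)",
         call. = FALSE)
  if (full$n != restricted$n)
    stop("fits use different numbers of rows", call. = FALSE)
  if (is.null(df)) df <- ncol(full$X) - ncol(restricted$X)
  stat <- max(2 * (full$logLik - restricted$logLik), 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Robust random-intercept fit by Huber reweighting
#'
#' Sensitivity-analysis companion to [fit_mlm()]: iteratively reweighted
#' fitting with Huber weights (tuning constant `c = 1.345`) on the scaled
#' conditional residuals, so gross response outliers are downweighted while
#' clean observations keep weight ~1. This is a Huber-type reweighting
#' scheme, a documented simplification of full robust mixed-model
#' estimators.
#'
#' @inheritParams fit_mlm
#' @param tune Huber tuning constant.
#' @param max_iter,tol iteration control.
#' @return an `mlm_fit` with `method = "robust"` and a `robust_weights`
#'   field.
#' @export
fit_robust_mlm <- function(y, X, groups, tune = 1.345, max_iter = 30,
                           tol = 1e-6) {
  X <- as.matrix(X)
  w <- rep(1, length(y))
  fit <- fit_mlm(y, X, groups, method = "REML")
  for (it in seq_len(max_iter)) {
    beta_old <- fit$coefficients$estimate
    e <- fit$residuals             # conditional residuals (BLUP-corrected)
    s <- sqrt(fit$sigma2_resid)
    u <- abs(e) / max(s, 1e-12)
    w <- ifelse(u <= tune, 1, tune / u)
    fit <- fit_mlm(y, X, groups, method = "REML", weights = w)
    if (max(abs(fit$coefficients$estimate - beta_old)) < tol) break
  }
  fit$method <- "robust"
  fit$robust_weights <- w
  fit
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept linear mixed model (%s)\n", x$method))
  cat(sprintf("  n = %d observations in %d groups\n", x$n, x$ngroups))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("  sigma2_patient = %.4g, sigma2_resid = %.4g\n",
              x$sigma2_patient, x$sigma2_resid))
  cat(sprintf("  logLik = %.3f, marginal R2 = %.3f\n",
              x$logLik, x$marginal_r2))
  invisible(x)
}
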