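#' Fit a linear or quadratic random-intercept association model
#'
#' `y ~ x` or `y ~ x + x^2` with a patient random intercept; the quadratic
#' column is centered before squaring for numerical stability. Returns an
#' `mlm_fit` (REML) whose marginal R-squared measures the strength of the
#' association.
#'
#' @param y,x numeric vectors (n >= 10).
#' @param groups patient ids.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return an `mlm_fit`.
#' @export
fit_association <- function(y, x, groups, degree = 2) {
  stopifnot(length(y) >= 10, degree %in% c(1, 2))
  xc <- x - mean(x)
  X <- if (degree == 2) cbind(`(Intercept)` = 1, x = xc, x2 = xc^2)
       else cbind(`(Intercept)` = 1, x = xc)
  fit_mlm(y, X, groups, method = "REML")
}

#' Residual diagnostics for an association fit
#'
#' Standardized conditional residuals against fitted values, with trend
#' statistics summarizing lack of fit: the correlation of the residuals
#' with the fitted values (`trend_linear`, ~0 by construction for a
#' least-squares-like fit) and with the squared centered fitted values
#' (`trend_quadratic`, large when a linear model is fitted to curved
#' data).
#'
#' @param fit an `mlm_fit`.
#' @return list with `table` (data.frame: fitted, std_resid, group) and
#'   the two trend statistics.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "mlm_fit"))
  sr <- fit$residuals / sqrt(fit$sigma2_resid)
  ft <- fit$fitted
  fc2 <- (ft - mean(ft))^2
  t1 <- if (sd(ft) > 1e-12 && sd(sr) > 1e-12) cor(sr, ft) else 0
  t2 <- if (sd(fc2) > 1e-12 && sd(sr) > 1e-12) cor(sr, fc2) else 0
  list(table = data.frame(fitted = ft, std_resid = sr,
                          group = fit$groups),
       trend_linear = t1, trend_quadratic = t2)
}

#' Association triangle: maf, LDH and the radiomics signature
#'
#' Fits the three pairwise random-intercept models — log(maf) ~ signature,
#' log(maf) ~ LDH, signature ~ LDH — each in a linear and a quadratic
#' variant. The model form is chosen automatically: the quadratic variant
#' is kept when the linear fit's quadratic residual trend exceeds
#' `trend_threshold` (in absolute value), mirroring choosing the form from
#' the standardized-residual-vs-fitted plot; the choice is recorded and
#' can be read off the report. Pairs with marginal R-squared below
#' `independence_threshold` are flagged as near-independent. LDH values
#' are additionally flagged against the upper limit of normal.
#'
#' @param cohort data.frame with `log_maf`, `ldh`, `patient_id` and the
#'   signature features.
#' @param signature a `signature_model` evaluated on the cohort rows.
#' @param ldh_uln upper limit of normal for LDH (U/L).
#' @param trend_threshold quadratic-trend cutoff for keeping the quadratic
#'   form.
#' @param independence_threshold marginal R-squared below which a pair is
#'   flagged near-independent.
#' @return object of class `association_report`: per pair, both fits,
#'   their marginal R-squared, the chosen degree and diagnostics; plus
#'   `ldh_above_uln` flags and a `warnings` field for skipped pairs.
#' @export
association_triangle <- function(cohort, signature, ldh_uln = 246,
                                 trend_threshold = 0.1,
                                 independence_threshold = 0.1) {
  stopifnot(all(c("log_maf", "patient_id") %in% names(cohort)))
  sig <- evaluate_signature(signature, cohort)
  g <- cohort$patient_id
  warnings <- character(0)

  pair <- function(y, x, label) {
    bad <- is.na(y) | is.na(x)
    if (all(bad) || length(unique(x[!bad])) < 2 ||
        length(unique(y[!bad])) < 2) {
      warnings <<- c(warnings, sprintf("pair '%s' skipped (degenerate data)",
                                       label))
      return(NULL)
    }
    yy <- y[!bad]; xx <- x[!bad]; gg <- g[!bad]
    lin <- fit_association(yy, xx, gg, degree = 1)
    quad <- fit_association(yy, xx, gg, degree = 2)
    dl <- residual_diagnostics(lin)
    dq <- residual_diagnostics(quad)
    chosen <- if (abs(dl$trend_quadratic) > trend_threshold) 2 else 1
    r2 <- c(linear = lin$marginal_r2, quadratic = quad$marginal_r2)
    list(label = label, linear = lin, quadratic = quad,
         marginal_r2 = r2, chosen_degree = chosen,
         chosen_r2 = unname(r2[chosen]),
         diagnostics = list(linear = dl, quadratic = dq),
         near_independent = unname(r2[chosen]) < independence_threshold)
  }

  has_ldh <- "ldh" %in% names(cohort) && any(!is.na(cohort$ldh))
  if (!has_ldh)
    warnings <- c(warnings, "LDH column missing or empty; partial report")
  models <- list(
    maf_signature = pair(cohort$log_maf, sig, "log(maf) ~ signature"),
    maf_ldh = if (has_ldh) pair(cohort$log_maf, cohort$ldh,
                                "log(maf) ~ LDH") else NULL,
    signature_ldh = if (has_ldh) pair(sig, cohort$ldh,
                                      "signature ~ LDH") else NULL)
  structure(list(models = models,
                 signature_values = sig,
                 ldh_above_uln = if (has_ldh) cohort$ldh > ldh_uln else NULL,
                 ldh_uln = ldh_uln,
                 warnings = warnings),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("Association triangle (random-intercept models)\n")
  for (m in x$models) {
    if (is.null(m)) next
    cat(sprintf(
      "  %-24s marginal R2 = %.3f (degree %d%s)\n", m$label,
      m$chosen_r2, m$chosen_degree,
      if (m$near_independent) "; near-independent" else ""))
  }
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}
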