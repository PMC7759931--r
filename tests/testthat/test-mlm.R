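# Mixed-model core: cross-checks against lme4/lmerTest (the independent
# reference implementation), degenerate limits and the robust variant.

sim_grouped <- function(seed = 1, npat = 12, icc = 0.4, beta = c(1, 0.5),
                        sigma = 0.7) {
  set.seed(seed)
  sizes <- sample(2:8, npat, replace = TRUE)
  g <- rep(seq_len(npat), sizes)
  n <- length(g)
  x <- rnorm(n)
  sdb <- sigma * sqrt(icc / (1 - icc))
  y <- beta[1] + beta[2] * x + rnorm(npat, sd = sdb)[g] +
    rnorm(n, sd = sigma)
  list(y = y, X = cbind(1, x = x), g = g)
}

test_that("REML fit agrees with lmerTest (coefficients, variances, df)", {
  skip_if_not_installed("lmerTest")
  d <- sim_grouped(2)
  fit <- fit_mlm(d$y, d$X, d$g)
  lf <- lmerTest::lmer(y ~ x + (1 | g),
                       data = data.frame(y = d$y, x = d$X[, 2], g = d$g))
  sm <- summary(lf)$coefficients
  expect_equal(fit$coefficients$estimate, unname(sm[, "Estimate"]),
               tolerance = 1e-5)
  expect_equal(fit$coefficients$se, unname(sm[, "Std. Error"]),
               tolerance = 1e-5)
  expect_equal(fit$coefficients$df, unname(sm[, "df"]), tolerance = 1e-2)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma2_patient, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-5)
  expect_equal(fit$logLik, as.numeric(logLik(lf)), tolerance = 1e-6)

  fitml <- fit_mlm(d$y, d$X, d$g, method = "ML")
  lfm <- lme4::lmer(y ~ x + (1 | g), REML = FALSE,
                    data = data.frame(y = d$y, x = d$X[, 2], g = d$g))
  expect_equal(fitml$logLik, as.numeric(logLik(lfm)), tolerance = 1e-6)
})

test_that("with no between-patient variance the fit reduces to OLS", {
  set.seed(4)
  npat <- 10
  g <- rep(1:npat, each = 6)
  x <- rnorm(60)
  e <- rnorm(60)
  # remove group-mean structure from the errors so the REML estimate of
  # the patient variance sits at the boundary
  e <- e - ave(e, g)
  y <- 1 + 0.5 * x + e
  fit <- fit_mlm(y, cbind(1, x), g)
  ols <- coef(lm(y ~ x))
  expect_lt(max(abs(fit$coefficients$estimate - ols)), 1e-6)
  expect_lt(fit$sigma2_patient, 1e-8)
})

test_that("one observation per group matches OLS and ~zero patient variance", {
  set.seed(5)
  n <- 40
  x <- rnorm(n)
  y <- 2 - 0.3 * x + rnorm(n)
  fit <- fit_mlm(y, cbind(1, x), seq_len(n))
  expect_lt(max(abs(fit$coefficients$estimate - coef(lm(y ~ x)))), 1e-6)
})

test_that("noise-free response gives exact coefficients and ~zero residual variance", {
  set.seed(6)
  g <- rep(1:8, each = 4)
  x <- rnorm(32)
  y <- 2 + 3 * x
  fit <- fit_mlm(y, cbind(1, x), g)
  expect_equal(fit$coefficients$estimate, c(2, 3), tolerance = 1e-8)
  expect_lt(fit$sigma2_resid, 1e-10)
})

test_that("rank-deficient designs are rejected", {
  d <- sim_grouped(7)
  X <- cbind(d$X, d$X[, 2])
  expect_error(fit_mlm(d$y, X, d$g), "rank deficient")
})

test_that("profiled REML objective is maximal at the reported optimum", {
  d <- sim_grouped(8)
  prep <- ctradiomics:::.mlm_prep(d$y, d$X, d$g)
  fit <- fit_mlm(d$y, d$X, d$g)
  dev_opt <- ctradiomics:::.mlm_deviance(prep, fit$theta, reml = TRUE)
  set.seed(1)
  for (r in 1:100) {
    th <- fit$theta * exp(runif(1, -2, 2)) + runif(1, 0, 0.5)
    expect_gte(ctradiomics:::.mlm_deviance(prep, th, TRUE) + 1e-8, dev_opt)
  }
})

test_that("marginal R2 follows its variance decomposition", {
  expect_equal(marginal_r2(var_fixed = 3, sigma2_patient = 1,
                           sigma2_resid = 1), 0.6)
  d <- sim_grouped(9)
  null_fit <- fit_mlm(d$y, d$X[, 1, drop = FALSE], d$g)
  expect_equal(null_fit$marginal_r2, 0)
  # noise-free: R2 -> 1
  g <- rep(1:6, each = 5)
  x <- rnorm(30)
  f <- fit_mlm(1 + 2 * x, cbind(1, x), g)
  expect_gt(f$marginal_r2, 0.999)
})

test_that("LRT: zero for identical models, chi-square tail, REML rejected", {
  d <- sim_grouped(10)
  full <- fit_mlm(d$y, d$X, d$g, method = "ML")
  expect_equal(lrt(full, full, df = 1)$statistic, 0)
  expect_equal(lrt(full, full, df = 1)$p, 1)
  restricted <- fit_mlm(d$y, d$X[, 1, drop = FALSE], d$g, method = "ML")
  res <- lrt(full, restricted)
  expect_equal(res$df, 1)
  expect_gte(res$statistic, 0)
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  fr <- fit_mlm(d$y, d$X, d$g, method = "REML")
  expect_error(lrt(fr, restricted), "REML")
})

test_that("LRT statistic is non-negative across random nested simulations", {
  set.seed(11)
  worst <- 0
  for (r in 1:200) {
    d <- sim_grouped(seed = 1000 + r, npat = 8)
    z <- rnorm(length(d$y))
    full <- fit_mlm(d$y, cbind(d$X, z), d$g, method = "ML",
                    ddf = "residual")
    restr <- fit_mlm(d$y, d$X, d$g, method = "ML", ddf = "residual")
    stat <- 2 * (full$logLik - restr$logLik)
    worst <- min(worst, stat)
  }
  expect_gte(worst, -1e-6)
})

test_that("robust fit downweights a gross outlier and tracks REML on clean data", {
  d <- sim_grouped(12, npat = 15)
  clean <- fit_mlm(d$y, d$X, d$g)
  rob <- fit_robust_mlm(d$y, d$X, d$g)
  expect_lt(max(abs(rob$coefficients$estimate -
                      clean$coefficients$estimate) /
                  clean$coefficients$se), 2)
  expect_gt(mean(rob$robust_weights > 0.95), 0.8)

  y2 <- d$y
  y2[5] <- y2[5] + 10 * sd(d$y)
  plain <- fit_mlm(y2, d$X, d$g)
  rob2 <- fit_robust_mlm(y2, d$X, d$g)
  shift_plain <- abs(plain$coefficients$estimate[1] -
                       clean$coefficients$estimate[1])
  shift_rob <- abs(rob2$coefficients$estimate[1] -
                     clean$coefficients$estimate[1])
  expect_lt(shift_rob, 0.25 * shift_plain)
  expect_lt(rob2$robust_weights[5], 0.3)
})
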