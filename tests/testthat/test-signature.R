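# PCA radiomics signature: top-5 selection, fitting, evaluation,
# serialization.

test_that("top-5 selection takes the smallest LRT p among real features", {
  g <- generate_cohort(cohort_sim_config(seed = 31))
  sc <- screen_features(g$cohort,
                        setdiff(radiomic_feature_names(), "Volume"),
                        n_random = 20, adjust_volume = TRUE, seed = 1)
  top <- pick_top5(sc)
  expect_length(top, 5)
  expect_false(any(is_random_feature(top)))
  real <- sc[!sc$is_random & sc$feature != "Volume", ]
  real <- real[order(real$lrt_p, real$feature), ]
  expect_equal(top, real$feature[1:5])
  # unadjusted screen lacks LRT p-values
  sc0 <- screen_features(g$cohort, radiomic_feature_names(),
                         n_random = 5, seed = 1)
  expect_error(pick_top5(sc0), "LRT")
})

test_that("two perfectly correlated columns load at +-1/sqrt(2)", {
  set.seed(2)
  x <- rnorm(50)
  d <- data.frame(a = x, b = 2 * x + 3)
  m <- fit_pca_signature(d, c("a", "b"),
                         registry = list(.default =
                                           transform_spec("identity")))
  expect_equal(abs(unname(m$loadings)), rep(1 / sqrt(2), 2),
               tolerance = 1e-9)
  expect_equal(sum(m$loadings^2), 1, tolerance = 1e-12)
})

test_that("loadings match an eigen-decomposition oracle", {
  set.seed(3)
  n <- 200
  f <- rnorm(n)
  d <- data.frame(a = f + rnorm(n, sd = 0.3),
                  b = -f + rnorm(n, sd = 0.5),
                  c = 0.5 * f + rnorm(n, sd = 1))
  m <- fit_pca_signature(d, c("a", "b", "c"),
                         registry = list(.default =
                                           transform_spec("identity")))
  Z <- scale(as.matrix(d))
  ev <- eigen(cor(as.matrix(d)))
  oracle <- ev$vectors[, 1]
  # align signs before comparison
  if (sum(oracle * m$loadings) < 0) oracle <- -oracle
  expect_equal(unname(m$loadings), oracle, tolerance = 1e-9)
})

test_that("flipping one column's sign flips only that loading", {
  set.seed(4)
  f <- rnorm(100)
  d <- data.frame(a = f + rnorm(100, 0, 0.4),
                  b = f + rnorm(100, 0, 0.4),
                  c = f + rnorm(100, 0, 0.4))
  reg <- list(.default = transform_spec("identity"))
  y <- f
  m1 <- fit_pca_signature(d, c("a", "b", "c"), response = y,
                          registry = reg)
  d2 <- d; d2$b <- -d$b
  m2 <- fit_pca_signature(d2, c("a", "b", "c"), response = y,
                          registry = reg)
  expect_equal(unname(m1$loadings[c("a", "c")]),
               unname(m2$loadings[c("a", "c")]), tolerance = 1e-9)
  expect_equal(unname(m1$loadings["b"]), -unname(m2$loadings["b"]),
               tolerance = 1e-9)
})

test_that("evaluation reproduces the published worked example", {
  m <- signature_model(
    c("Correlation", "GLNUz", "StdDev", "LGRE", "Coarseness"),
    c(0.323, -0.528, 0.438, 0.383, 0.527))
  unit1 <- data.frame(Correlation = 1, GLNUz = 0, StdDev = 0, LGRE = 0,
                      Coarseness = 0)
  expect_equal(evaluate_signature(m, unit1), 0.323)
  zero <- data.frame(Correlation = 0, GLNUz = 0, StdDev = 0, LGRE = 0,
                     Coarseness = 0)
  expect_equal(evaluate_signature(m, zero), 0)
  ones <- data.frame(Correlation = 1, GLNUz = 1, StdDev = 1, LGRE = 1,
                     Coarseness = 1)
  expect_equal(evaluate_signature(m, ones), 1.143)
  expect_error(evaluate_signature(m, unit1[, -2]), "GLNUz")
})

test_that("signature is invariant to affine rescaling absorbed by the constants", {
  set.seed(5)
  f <- rnorm(80)
  d <- data.frame(a = f + rnorm(80, 0, 0.3), b = f + rnorm(80, 0, 0.3))
  reg <- list(.default = transform_spec("identity"))
  m <- fit_pca_signature(d, c("a", "b"), response = f, registry = reg)
  s1 <- evaluate_signature(m, d)
  d2 <- data.frame(a = 5 * d$a - 2, b = 0.1 * d$b + 7)
  m2 <- fit_pca_signature(d2, c("a", "b"), response = f, registry = reg)
  s2 <- evaluate_signature(m2, d2)
  expect_equal(abs(cor(s1, s2)), 1, tolerance = 1e-9)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("JSON round-trip preserves the model and its evaluations", {
  g <- generate_cohort(cohort_sim_config(seed = 32))
  m <- fit_pca_signature(g$cohort,
                         c("Correlation", "GLNUz", "StdDev", "LGRE",
                           "Coarseness"),
                         response = abs(g$cohort$log_maf))
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_json(m, path)
  m2 <- read_signature_json(path)
  expect_equal(evaluate_signature(m, g$cohort),
               evaluate_signature(m2, g$cohort), tolerance = 1e-12)
})

test_that("signature of a shared-factor quintet beats each single feature", {
  wins <- 0
  nrep <- 30
  for (r in seq_len(nrep)) {
    set.seed(600 + r)
    npat <- 15; visits <- 5
    g <- rep(seq_len(npat), each = visits)
    n <- length(g)
    f <- rnorm(n) + rnorm(npat, sd = 0.5)[g]   # latent heterogeneity
    F5 <- sapply(1:5, function(j) f + rnorm(n, sd = 1))
    colnames(F5) <- paste0("S", 1:5)
    y <- f + rnorm(npat, sd = 0.4)[g] + rnorm(n, sd = 0.7)
    d <- as.data.frame(F5)
    reg <- list(.default = transform_spec("identity"))
    m <- fit_pca_signature(d, colnames(F5), response = y,
                           registry = reg)
    s <- evaluate_signature(m, d)
    r2_sig <- fit_mlm(y, cbind(1, s), g)$marginal_r2
    r2_single <- vapply(1:5, function(j)
      fit_mlm(y, cbind(1, F5[, j]), g)$marginal_r2, numeric(1))
    if (r2_sig > max(r2_single)) wins <- wins + 1
  }
  expect_gt(wins / nrep, 0.5)
})
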