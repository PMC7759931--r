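# Monte-Carlo null reference machinery.

test_that("joint structure estimation is consistent and repairs PSD", {
  set.seed(1)
  n <- 500
  F0 <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  v <- rnorm(n)
  st <- estimate_joint_structure(F0, v)
  offdiag <- st$cov[1:4, 1:4][upper.tri(diag(4))]
  expect_lt(max(abs(offdiag)), 0.15)
  expect_false(st$clipped)

  # perfectly collinear pair triggers the clip
  F2 <- cbind(a = F0[, 1], b = F0[, 1])
  st2 <- estimate_joint_structure(F2, v)
  expect_true(st2$clipped)
  expect_error(estimate_joint_structure(cbind(F0[, 1], NA), v), "missing")
})

test_that("estimated covariance converges to a known factor structure", {
  set.seed(2)
  errs <- vapply(c(200, 800, 3200), function(n) {
    f <- rnorm(n)
    X <- sapply(1:3, function(j) 0.8 * f + sqrt(1 - 0.64) * rnorm(n))
    colnames(X) <- paste0("x", 1:3)
    v <- 0.6 * f + 0.8 * rnorm(n)
    st <- estimate_joint_structure(X, v)
    Ctrue <- rbind(cbind(matrix(0.64, 3, 3) + diag(0.36, 3), 0.48),
                   c(rep(0.48, 3), 1))
    norm(st$cov - Ctrue, "F")
  }, numeric(1))
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 0.15)
})

test_that("simulated null features match the target volume correlation and zero response correlation", {
  set.seed(3)
  n <- 300
  v <- rnorm(n)
  f <- 0.8 * v + 0.6 * rnorm(n)
  X <- cbind(f1 = f, f2 = 0.8 * v + 0.6 * rnorm(n),
             f3 = rnorm(n), f4 = rnorm(n), f5 = rnorm(n))
  st <- estimate_joint_structure(X, v)
  y <- 2 * v + rnorm(n)   # a response the generator never sees
  cfg <- null_sim_config(n_datasets = 200, n_features = 5, seed = 7)
  gen <- simulate_null_features(st, v, cfg)
  cors_v <- numeric(200); cors_y <- numeric(200)
  for (i in 1:200) {
    Fi <- gen(i)
    cors_v[i] <- cor(Fi[, 1], v)
    cors_y[i] <- cor(Fi[, 3], y)
  }
  expect_lt(abs(mean(cors_v) - cor(f, v)), 0.05)
  expect_lt(abs(mean(cors_y)), 2 / sqrt(n))
  # seeded determinism
  gen2 <- simulate_null_features(st, v, cfg)
  expect_identical(gen(5), gen2(5))
})

test_that("patient-dependent null features carry the configured ICC", {
  set.seed(4)
  pid <- rep(1:40, each = 10)
  n <- length(pid)
  v <- rnorm(n)
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n),
             e = rnorm(n))
  st <- estimate_joint_structure(X, v)
  cfg <- null_sim_config(n_datasets = 5, n_features = 5,
                         include_patient_dependence = TRUE, icc = 0.4,
                         seed = 8)
  gen <- simulate_null_features(st, v, cfg, patient_ids = pid)
  Fi <- gen(1)
  f <- fit_mlm(Fi[, 2], matrix(1, n, 1), pid)
  icc_hat <- f$sigma2_patient / (f$sigma2_patient + f$sigma2_resid)
  expect_lt(abs(icc_hat - 0.4), 0.12)
  expect_error(simulate_null_features(st, v, cfg), "patient_ids")
})

test_that("null reference test: add-one p bounds, guard, and a planted signal is detected", {
  feature_names <- paste0("G", 1:8)
  C <- diag(9)
  dimnames(C) <- list(c(feature_names, "Volume"),
                      c(feature_names, "Volume"))
  reg <- list(.default = transform_spec("identity"))
  cfg0 <- cohort_sim_config(n_patients = 15, visit_mean = 5,
                            feature_cov = C, seed = 41)
  g0 <- generate_cohort(cfg0, registry = reg)
  nt <- null_reference_test(g0$cohort, feature_names,
                            null_sim_config(n_datasets = 60,
                                            n_features = 8, top_k = 3,
                                            seed = 1),
                            registry = reg)
  expect_gte(nt$p_r2, 1 / 61)
  expect_lte(nt$p_r2, 1)
  expect_equal(nrow(nt$null), 60)
  expect_error(null_reference_test(g0$cohort, feature_names,
                                   null_sim_config(60, 8),
                                   registry = reg, reselect = FALSE),
               "anti-conservative")

  # strong planted 3-feature signal: small empirical p
  cfgs <- cohort_sim_config(n_patients = 15, visit_mean = 5,
                            feature_cov = C,
                            beta_features = c(G1 = 0.8, G2 = 0.8,
                                              G3 = 0.8),
                            sigma_resid = 0.5, seed = 42)
  gs <- generate_cohort(cfgs, registry = reg)
  nts <- null_reference_test(gs$cohort, feature_names,
                             null_sim_config(n_datasets = 99,
                                             n_features = 8, top_k = 3,
                                             seed = 2),
                             registry = reg)
  expect_lte(nts$p_lrt, 0.05)
  # determinism
  nts2 <- null_reference_test(gs$cohort, feature_names,
                              null_sim_config(n_datasets = 99,
                                              n_features = 8, top_k = 3,
                                              seed = 2),
                              registry = reg)
  expect_identical(nts$null, nts2$null)
})

test_that("signature builder scores the null cloud too", {
  feature_names <- paste0("G", 1:6)
  C <- diag(7)
  dimnames(C) <- list(c(feature_names, "Volume"),
                      c(feature_names, "Volume"))
  reg <- list(.default = transform_spec("identity"))
  g <- generate_cohort(cohort_sim_config(n_patients = 12, visit_mean = 5,
                                         feature_cov = C, seed = 43),
                       registry = reg)
  nt <- null_reference_test(g$cohort, feature_names,
                            null_sim_config(n_datasets = 40,
                                            n_features = 6, top_k = 3,
                                            seed = 3),
                            builder = "signature", registry = reg)
  expect_true(all(is.finite(nt$null$r2)))
  expect_true(all(nt$null$lrt >= 0))
})
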