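# Synthetic cohort generator: parameter recovery, reproducibility, and the
# blood-offset calibration.

test_that("config validation catches bad covariances and ICCs", {
  C <- default_feature_cov()
  expect_true(isSymmetric(unname(C)))
  bad <- C; bad[1, 2] <- 5
  expect_error(cohort_sim_config(feature_cov = bad), "symmetric")
  bad2 <- matrix(c(1, 0.99, 0.99, 0.99, 1, -0.99, 0.99, -0.99, 1), 3, 3,
                 dimnames = list(c("a", "b", "Volume"),
                                 c("a", "b", "Volume")))
  expect_error(cohort_sim_config(feature_cov = bad2),
               "positive semi-definite")
  expect_error(cohort_sim_config(icc_patient = 1))
  expect_error(cohort_sim_config(n_patients = 1))
})

test_that("generation is bit-reproducible given the seed", {
  g1 <- generate_cohort(cohort_sim_config(seed = 42))
  g2 <- generate_cohort(cohort_sim_config(seed = 42))
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$blood, g2$blood)
  g3 <- generate_cohort(cohort_sim_config(seed = 43))
  expect_false(identical(g1$cohort$maf, g3$cohort$maf))
})

test_that("cohort scale matches the configured study shape", {
  g <- generate_cohort(cohort_sim_config(seed = 1))
  expect_equal(length(unique(g$cohort$patient_id)), 15)
  expect_true(nrow(g$cohort) > 40 && nrow(g$cohort) < 110)
  expect_true(all(g$cohort$maf > 0 & g$cohort$maf <= 1))
  expect_true(all(table(g$cohort$patient_id) >= 1 &
                    table(g$cohort$patient_id) <= 12))
})

test_that("response ICC is recovered at large n and vanishes at icc 0", {
  big <- cohort_sim_config(n_patients = 50, visit_mean = 20,
                           visit_range = c(20, 20), icc_patient = 0.4,
                           sigma_resid = 0.8, seed = 2)
  g <- generate_cohort(big)
  # empirical ICC of the response after removing the volume effect
  r <- g$cohort$log_maf - g$truth$beta_volume * g$cohort$log_volume
  f <- fit_mlm(r, matrix(1, nrow(g$cohort), 1), g$cohort$patient_id)
  icc_hat <- f$sigma2_patient / (f$sigma2_patient + f$sigma2_resid)
  expect_lt(abs(icc_hat - 0.4), 0.05)

  g0 <- generate_cohort(cohort_sim_config(
    n_patients = 50, visit_mean = 20, visit_range = c(20, 20),
    icc_patient = 0, seed = 3))
  r0 <- g0$cohort$log_maf - g0$truth$beta_volume * g0$cohort$log_volume
  f0 <- fit_mlm(r0, matrix(1, nrow(g0$cohort), 1), g0$cohort$patient_id)
  icc0 <- f0$sigma2_patient / (f0$sigma2_patient + f0$sigma2_resid)
  expect_lt(icc0, 0.05)
})

test_that("beta_volume = 0 with tiny noise gives a per-patient constant response", {
  g <- generate_cohort(cohort_sim_config(beta_volume = 0,
                                         sigma_resid = 1e-6,
                                         icc_patient = 0.5, seed = 4))
  spread <- tapply(g$cohort$log_maf, g$cohort$patient_id,
                   function(v) diff(range(v)))
  expect_lt(max(spread), 1e-4)
})

test_that("feature correlations converge to the target structure", {
  C <- default_feature_cov(feature_names = c("A", "B", "C", "D"))
  cfg <- cohort_sim_config(n_patients = 100, visit_mean = 20,
                           visit_range = c(20, 20), feature_cov = C,
                           feature_icc = 0.3, seed = 5)
  reg <- list(.default = transform_spec("identity"))
  g <- generate_cohort(cfg, registry = reg)
  Z <- cbind(as.matrix(g$features[, c("A", "B", "C", "D")]),
             Volume = g$cohort$log_volume)
  emp <- cor(Z)
  expect_lt(max(abs(emp - C)), 0.1)
})

test_that("median absolute blood-imaging offset is about 10 days", {
  meds <- vapply(1:200, function(s) {
    g <- generate_cohort(cohort_sim_config(seed = 1000 + s))
    median(abs(g$truth$blood_offsets))
  }, numeric(1))
  expect_lt(abs(median(meds) - 10), 2)
})

test_that("spiked random predictors are reproducible, independent, and carry the requested ICC", {
  pid <- rep(1:40, each = 25)
  s1 <- spike_random_features(10, pid, icc = 0, seed = 9)
  s2 <- spike_random_features(10, pid, icc = 0, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(is_random_feature(names(s1))))

  # icc = 0: patient means vary only by sampling error
  pm <- tapply(s1[[1]], pid, mean)
  expect_lt(var(pm), 3 / 25)  # ~Var(mean of 25) = 1/25

  sicc <- spike_random_features(30, pid, icc = 0.4, seed = 10)
  iccs <- vapply(sicc, function(col) {
    f <- fit_mlm(col, matrix(1, length(pid), 1), pid)
    f$sigma2_patient / (f$sigma2_patient + f$sigma2_resid)
  }, numeric(1))
  expect_lt(abs(mean(iccs) - 0.4), 0.07)

  # independence from a response generated elsewhere
  y <- rnorm(length(pid))
  cors <- vapply(s1, function(col) cor(col, y), numeric(1))
  expect_lt(max(abs(cors)), 4 / sqrt(length(pid)))
})

test_that("planted feature effects enter the response as configured", {
  C <- default_feature_cov(feature_names = c("A", "B", "C", "D", "E"))
  diag_C <- diag(ncol(C)); dimnames(diag_C) <- dimnames(C)
  cfg <- cohort_sim_config(n_patients = 40, visit_mean = 8,
                           visit_range = c(5, 12), feature_cov = diag_C,
                           beta_features = c(A = 1.0), seed = 6)
  g <- generate_cohort(cfg, registry = list(.default =
                                              transform_spec("identity")))
  fit <- fit_mlm(g$cohort$log_maf,
                 cbind(1, g$cohort$A, g$cohort$log_volume),
                 g$cohort$patient_id)
  est <- fit$coefficients$estimate[2]
  se <- fit$coefficients$se[2]
  expect_lt(abs(est - 1.0), 4 * se)
})
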