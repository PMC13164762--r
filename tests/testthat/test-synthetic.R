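test_that("fixed seeds make generators bit-reproducible", {
  a <- sim_plasma_profiles(n_subjects = 5, route = "PO", seed = 123)
  b <- sim_plasma_profiles(n_subjects = 5, route = "PO", seed = 123)
  expect_identical(a, b)
  expect_identical(sim_calibration_batch(cv = 0.05, seed = 9),
                   sim_calibration_batch(cv = 0.05, seed = 9))
  expect_identical(sim_microsomal_decay(cv = 0.05, seed = 4),
                   sim_microsomal_decay(cv = 0.05, seed = 4))
})

test_that("zero variability produces identical subjects at the closed form", {
  profiles <- sim_plasma_profiles(n_subjects = 3, route = "IV", dose = 2.5,
                                  cv_cl = 0, cv_v = 0, cv_ka = 0,
                                  residual_cv = 0, seed = 1)
  expect_identical(profiles[[1]]$conc, profiles[[2]]$conc)
  expect_identical(profiles[[2]]$conc, profiles[[3]]$conc)
  # C(5 min) from the closed form: (2.5/1.2) mg/L * exp(-ke * 5/60)
  ke <- 0.23 / 1.2
  expect_equal(profiles[[1]]$conc[1],
               (2.5 / 1.2) * 1000 * exp(-ke * 5 / 60), tolerance = 1e-12)
  expect_equal(profiles[[1]]$conc[1], 2050, tolerance = 0.001)
})

test_that("LLOQ censoring never reports positive values below the limit", {
  profiles <- sim_plasma_profiles(n_subjects = 20, route = "PO", seed = 77)
  all_conc <- unlist(lapply(profiles, `[[`, "conc"))
  expect_true(all(all_conc == 0 | all_conc >= 0.2))
  expect_true(all(all_conc >= 0))
  # the censoring mechanism itself: with a high limit, early samples zero out
  hi <- sim_plasma_profiles(n_subjects = 5, route = "PO", lloq = 100,
                            seed = 77)
  hi_conc <- unlist(lapply(hi, `[[`, "conc"))
  expect_true(any(hi_conc == 0))
  expect_true(all(hi_conc == 0 | hi_conc >= 100))
})

test_that("every generator embeds its truth and round-trips its estimator", {
  # microsomal decay
  tc <- sim_microsomal_decay(k = 0.00468)
  expect_equal(attr(tc, "truth")$k, 0.00468)
  fit <- fit_monoexponential_decay(tc$time_min, tc$ratio)
  expect_equal(fit$k, 0.00468, tolerance = 1e-10)
  expect_equal(fit$t_half, 0.693 / 0.00468, tolerance = 1e-10)
  flat <- sim_microsomal_decay(k = 0, nadph = TRUE)
  expect_true(fit_monoexponential_decay(flat$time_min, flat$ratio)$stable)
  ctrl <- sim_microsomal_decay(k = 0.00468, nadph = FALSE)
  expect_true(all(ctrl$ratio == 1))

  # dialysis
  d <- sim_dialysis(fu = 0.057)
  expect_equal(dialysis_fu(d$donor, d$receiver), 0.057, tolerance = 1e-12)
  expect_equal(percent_bound(d$donor, d$receiver), 94.3, tolerance = 1e-10)

  # transwell, both assays (noiseless recovery <= 2% of truth)
  pam <- sim_pampa(papp = 7e-6)
  expect_lt(abs(pampa_papp(pam$cd_t, pam$ca_t) - 7e-6) / 7e-6, 0.02)
  flat_acceptor <- sim_pampa(papp = 0)
  expect_equal(flat_acceptor$ca_t, 0)
  caco <- sim_caco2(papp = 3e-6)
  expect_lt(abs(caco2_papp(caco$time_s, caco$conc,
                           c0 = attr(caco, "truth")$c0)$papp - 3e-6) / 3e-6,
            0.02)

  # calibration
  batch <- sim_calibration_batch()
  std <- batch[batch$sample_type == "standard", ]
  fit <- fit_calibration(data.frame(nominal = std$nominal,
                                    response = std$response))
  expect_equal(fit$slope, 0.023, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.006, tolerance = 1e-12)

  # plasma profiles: noiseless IV NCA recovers CL within 2%
  dense <- exp(seq(log(0.05), log(48), length.out = 50))
  p <- sim_plasma_profiles(n_subjects = 1, route = "IV", times = dense,
                           cv_cl = 0, cv_v = 0, cv_ka = 0, residual_cv = 0,
                           seed = 1)[[1]]
  res <- nca(p, "linear_up_log_down")
  expect_lt(abs(res$cl - attr(p, "truth")$cl) / attr(p, "truth")$cl, 0.02)
  expect_lt(abs(res$vz - attr(p, "truth")$v) / attr(p, "truth")$v, 0.02)
})

test_that("an injected QC bias is detected by the accuracy statistics", {
  batch <- sim_calibration_batch(qc_bias = c(HQC = 0.05), n_runs = 1)
  std <- batch[batch$sample_type == "standard", ]
  fit <- fit_calibration(data.frame(nominal = std$nominal,
                                    response = std$response))
  qc <- batch[batch$sample_type == "qc", ]
  bc <- back_calculate(fit, qc$response)
  res <- accuracy_precision(
    data.frame(level = qc$level, nominal = qc$nominal,
               run_id = qc$run_id, value = bc$conc), "intra_day")
  hqc <- res[res$level == "HQC", ]
  expect_equal(hqc$bias_pct, 5.0, tolerance = 0.01)
  others <- res[res$level != "HQC", ]
  expect_true(all(abs(others$bias_pct) < 0.5))
})

test_that("tissue generator embeds Kp truth recovered by the estimator", {
  plasma <- data.frame(time_h = c(2, 8, 24), conc = c(1467, 93, 1.6))
  tis <- sim_tissue_profile(plasma)
  truth <- attr(tis, "truth")$kp
  for (ts in names(truth)) {
    g <- tis[tis$tissue == ts, ]
    expect_equal(tissue_kp(g$content, plasma$conc),
                 rep(truth[[ts]], 3), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
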