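make_profile <- function(time, conc, dose = 2.5, route = "IV", lloq = 0.2) {
  pk_profile(time, conc, dose = dose, route = route, lloq = lloq)
}

test_that("Cmax/Tmax report the earliest observed maximum", {
  p <- make_profile(c(0.25, 0.5, 1, 2), c(1500, 2781, 2000, 900), route = "PO",
                    dose = 10)
  expect_equal(cmax_tmax(p), list(cmax = 2781, tmax = 0.5))
  iv <- make_profile(c(5 / 60, 0.25, 0.5, 1), c(4000, 3000, 2000, 1000))
  expect_equal(cmax_tmax(iv)$tmax, 5 / 60)
  tie <- make_profile(c(0.5, 1, 2, 4), c(100, 300, 300, 50), route = "PO",
                      dose = 10)
  expect_equal(cmax_tmax(tie)$tmax, 1)
})

test_that("trapezoidal AUC matches closed forms on both rules", {
  p <- make_profile(c(0, 1), c(100, 50))
  expect_equal(auc_trapezoid(p, "linear"), 75)
  expect_equal(auc_trapezoid(p, "linear_up_log_down"), 50 / log(2),
               tolerance = 1e-12)
  # linear rule is exact on piecewise-linear data: refining the grid over
  # the same interval (kink at t = 1 included in both) changes nothing
  t_dense <- seq(0.5, 4, by = 0.05)
  pw <- function(t) ifelse(t <= 1, 100 * t, 100 - 25 * (t - 1))
  p2 <- make_profile(t_dense, pw(t_dense), route = "PO", dose = 10)
  coarse <- make_profile(c(0.5, 1, 2, 3, 4), pw(c(0.5, 1, 2, 3, 4)),
                         route = "PO", dose = 10)
  expect_equal(auc_trapezoid(coarse, "linear"),
               auc_trapezoid(p2, "linear"), tolerance = 1e-9)
  # log rule is exact on mono-exponential segments
  tt <- c(0, 0.5, 1.5, 4, 9)
  mono <- make_profile(tt, 100 * exp(-0.3 * tt))
  expect_equal(auc_trapezoid(mono, "linear_up_log_down"),
               (100 / 0.3) * (1 - exp(-0.3 * 9)), tolerance = 1e-12)
})

test_that("AUC is additive and invariant to interpolated points", {
  tt <- c(0.1, 0.5, 1, 2, 4, 8)
  cc <- c(50, 400, 300, 150, 60, 10)
  p <- make_profile(tt, cc, route = "PO", dose = 10)
  whole <- auc_trapezoid(p, "linear")
  # additivity over adjacent intervals
  seg_sum <- sum(vapply(seq_len(length(tt) - 1), function(i) {
    diff(tt[i:(i + 1)]) * mean(cc[i:(i + 1)])
  }, numeric(1)))
  expect_equal(whole, seg_sum, tolerance = 1e-12)
  # inserting a point on the interpolant changes nothing
  t_new <- 3
  c_new <- approx(tt, cc, xout = t_new)$y
  p_aug <- make_profile(sort(c(tt, t_new)),
                        c(cc[tt < t_new], c_new, cc[tt > t_new]),
                        route = "PO", dose = 10)
  expect_equal(auc_trapezoid(p_aug, "linear"), whole, tolerance = 1e-12)
})

test_that("terminal slope search recovers exact and noisy tails", {
  tt <- c(5 / 60, 0.25, 0.5, 1, 2, 4, 8, 24)
  p <- make_profile(tt, 4000 * exp(-0.21 * tt))
  lz <- select_lambda_z(p)
  expect_equal(lz$lambda_z, 0.21, tolerance = 1e-10)
  expect_equal(lz$adj_r2, 1, tolerance = 1e-10)
  expect_equal(log(2) / lz$lambda_z, 3.3, tolerance = 0.01)

  rising <- make_profile(c(1, 2, 4, 8), c(10, 20, 40, 80), route = "PO",
                         dose = 10)
  expect_true(select_lambda_z(rising)$no_terminal_phase)

  set.seed(5)
  tail_t <- c(1, 2, 4, 8, 12, 24)
  noisy <- make_profile(tail_t,
                        3000 * exp(-0.21 * tail_t) *
                          (1 + stats::rnorm(6, 0, 0.10)))
  lzn <- select_lambda_z(noisy)
  expect_lt(abs(lzn$lambda_z - 0.21) / 0.21, 0.15)
})

test_that("NCA recovers one-compartment IV truth within 2%", {
  cl <- 0.23; v <- 1.2; dose <- 2.5
  tt <- exp(seq(log(0.05), log(48), length.out = 60))
  p <- make_profile(tt, one_cpt_iv(tt, dose, cl, v), dose = dose)
  res <- nca(p, auc_method = "linear_up_log_down")
  ke <- cl / v
  expect_lt(abs(res$auc_inf - 1000 * (dose / v) / ke) /
              (1000 * (dose / v) / ke), 0.02)
  expect_lt(abs(res$cl - cl) / cl, 0.02)
  expect_lt(abs(res$vz - v) / v, 0.02)
  expect_lt(abs(res$t_half - log(2) / ke) / (log(2) / ke), 0.02)
  # internal consistency: CL * AUC_inf = dose, Vz * lambda_z = CL
  expect_equal(res$cl * res$auc_inf / 1000, dose, tolerance = 0.005)
  expect_equal(res$vz * res$lambda_z, res$cl, tolerance = 1e-10)
  expect_error(nca(make_profile(c(1, 2, 3), c(0, 0, 0))), "quantifiable")
})

test_that("bioavailability is the dose-normalized AUC ratio", {
  expect_equal(bioavailability(6803, 11608, dose_po = 10, dose_iv = 2.5),
               14.65, tolerance = 1e-3)
  expect_equal(round(bioavailability(6803, 11608, dose_po = 10,
                                     dose_iv = 2.5)), 15)
  expect_equal(bioavailability(1000, 2000, dose_po = 5, dose_iv = 10), 100)
  # identity: any profile against itself
  tt <- exp(seq(log(0.05), log(24), length.out = 30))
  p <- make_profile(tt, one_cpt_iv(tt, 2.5, 0.23, 1.2))
  r <- nca(p)
  expect_equal(bioavailability(r, r), 100)
})

test_that("oral normalization and hepatic-flow fraction are consistent", {
  expect_equal(normalize_oral_by_f(1.53, 0.15), 0.2295, tolerance = 1e-10)
  expect_equal(round(normalize_oral_by_f(1.53, 0.15), 2), 0.23)
  expect_equal(normalize_oral_by_f(5, 1), 5)
  expect_error(normalize_oral_by_f(1, 0), "\\(0, 1\\]")

  expect_equal(fraction_of_hepatic_flow(0.23, 3.6), 100 * 0.23 / 3.6)
  expect_equal(round(fraction_of_hepatic_flow(0.23, 3.6)), 6)
  expect_equal(fraction_of_hepatic_flow(3.6, 3.6), 100)
  expect_equal(fraction_of_hepatic_flow(0, 3.6), 0)
})

test_that("group summaries use per-subject mean and sample SD", {
  tt <- exp(seq(log(0.05), log(24), length.out = 25))
  profiles <- lapply(c(0.2, 0.3), function(cl) {
    make_profile(tt, one_cpt_iv(tt, 2.5, cl, 1.2))
  })
  summ <- summarize_nca(lapply(profiles, nca))
  cl_row <- summ[summ$parameter == "cl", ]
  expect_equal(cl_row$n, 2)
  expect_equal(cl_row$mean, 0.25, tolerance = 0.01)
  expect_equal(cl_row$sd, 0.0707, tolerance = 0.05)
  single <- summarize_nca(list(nca(profiles[[1]])))
  expect_true(all(is.na(single$sd)))
})
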