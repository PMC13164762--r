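test_that("log-linear decay fit recovers exact mono-exponential data", {
  times <- c(0, 5, 10, 20, 30, 45, 60)
  fit <- fit_monoexponential_decay(times, exp(-0.00468 * times))
  expect_equal(fit$k, 0.00468, tolerance = 1e-12)
  expect_equal(fit$t_half, 0.693 / 0.00468, tolerance = 1e-10)
  expect_equal(fit$t_half, 148, tolerance = 0.001)
  expect_false(fit$stable)

  flat <- fit_monoexponential_decay(times, rep(1, length(times)))
  expect_true(flat$stable)
  expect_identical(flat$t_half, Inf)

  expect_error(fit_monoexponential_decay(times, c(1, 1, 1, 1, 1, 0, 1)),
               "log-domain")
})

test_that("noisy decay estimation is unbiased: Monte-Carlo mean k within 10%", {
  # a single 7-point course at 5% CV has ~20% sampling error on k (slow
  # depletion over 60 min), so the recovery property is checked on the
  # Monte-Carlo mean over replicate incubations
  ks <- vapply(1:200, function(s) {
    tc <- sim_microsomal_decay(k = 0.00468, cv = 0.05, seed = s)
    fit_monoexponential_decay(tc$time_min, tc$ratio)$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.00468) / 0.00468, 0.10)
})

test_that("intrinsic clearance follows the half-life formula", {
  expect_equal(clint_from_halflife(148, 0.5, 0.25),
               (0.693 / 148) * 2, tolerance = 1e-12)
  expect_equal(clint_from_halflife(148, 0.5, 0.25), 0.00936, tolerance = 1e-3)
  expect_lt(clint_from_halflife(1e9), 1e-8)  # t1/2 -> Inf gives CL_int -> 0
  expect_equal(clint_from_halflife(100, 1.0, 0.25),
               2 * clint_from_halflife(100, 0.5, 0.25))  # linear in volume
  expect_error(clint_from_halflife(0), "positive")
})

test_that("liver scaling applies the species physiology factors", {
  expect_equal(scale_clint_to_liver(0.0152, species_scaling("mouse")),
               0.0152 * 45 * 60)
  expect_equal(scale_clint_to_liver(0.0152, species_scaling("mouse")),
               41.0, tolerance = 0.002)
  expect_equal(scale_clint_to_liver(0.00875, species_scaling("human")),
               7.0, tolerance = 1e-10)
  expect_equal(scale_clint_to_liver(0, species_scaling("mouse")), 0)
})

test_that("microsomal fraction unbound is the logP logistic", {
  expect_equal(fraction_unbound_microsomes(2.3),
               1 / (1 + 10^(0.53 * 2.3 - 1.42)), tolerance = 1e-12)
  expect_equal(fraction_unbound_microsomes(2.3), 0.613, tolerance = 0.002)
  expect_equal(fraction_unbound_microsomes(0),
               1 / (1 + 10^(-1.42)), tolerance = 1e-12)
  expect_equal(fraction_unbound_microsomes(0), 0.963, tolerance = 0.001)
  # strictly decreasing, onto (0, 1)
  lp <- seq(-10, 12, by = 0.5)
  fu <- fraction_unbound_microsomes(lp)
  expect_true(all(diff(fu) < 0))
  expect_true(all(fu > 0 & fu < 1))
  expect_lt(fraction_unbound_microsomes(30), 1e-10)
})

test_that("well-stirred clearance reproduces the worked mouse prediction", {
  cl <- well_stirred_clearance(41, 0.025, fraction_unbound_microsomes(2.3), 90)
  expect_equal(signif(cl, 2), 1.6)
  expect_equal(well_stirred_clearance(0, 0.025, 0.6, 90), 0)
  # flow-limited ceiling
  expect_equal(well_stirred_clearance(1e12, 1, 1e-3 + 0.999, 90), 90,
               tolerance = 1e-6)
  expect_lt(well_stirred_clearance(1e6, 0.5, 0.5, 90), 90)
})

test_that("the IVIVE chain is monotone in CL_int and bounded by Q", {
  fu_inc <- fraction_unbound_microsomes(2.3)
  clints <- seq(0.001, 0.2, length.out = 40)
  preds <- vapply(clints, function(ci) {
    ivive_chain(clint = ci, scaling = species_scaling("mouse"),
                logp = 2.3, fu_plasma = 0.025)$clh_predict
  }, numeric(1))
  expect_true(all(diff(preds) > 0))
  expect_true(all(preds < 90))
  # extraction-limited closed form at low intrinsic clearance
  small <- ivive_chain(clint = 1e-5, scaling = species_scaling("mouse"),
                       logp = 2.3, fu_plasma = 0.025)
  expect_equal(small$clh_predict,
               0.025 * small$clh_int / fu_inc, tolerance = 1e-3)
  # monotone in fu_plasma as well
  fus <- seq(0.01, 1, length.out = 20)
  pf <- vapply(fus, function(fp) {
    well_stirred_clearance(41, fp, fu_inc, 90)
  }, numeric(1))
  expect_true(all(diff(pf) > 0))
})

test_that("the chain runs from a half-life and skips prediction without Q", {
  res <- ivive_chain(t_half = 101, scaling = species_scaling("mouse"),
                     logp = 2.3, fu_plasma = 0.025)
  expect_equal(res$clint, clint_from_halflife(101))
  expect_equal(res$clh_int, res$clint * 45 * 60)
  expect_true(is.finite(res$clh_predict))

  human <- ivive_chain(t_half = 148, scaling = species_scaling("human"),
                       logp = 2.3, fu_plasma = 0.025)
  expect_true(is.na(human$clh_predict))  # no default human blood flow
  expect_equal(human$clh_int, clint_from_halflife(148) * 32 * 25)

  expect_error(ivive_chain(t_half = 100, clint = 0.01, logp = 2.3),
               "exactly one")
})
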