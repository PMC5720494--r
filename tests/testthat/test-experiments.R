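# Study designs: scans, sensitivity, calibration mechanics.

test_that("ktt = 1 scan point equals the unperturbed period", {
  m <- test_model()
  sc <- ktt_scan(m, "WT", ktt_grid = 1, onset = 12, out_dt = 0.02,
                 horizon = 140)
  base <- estimate_period_transient(wt_traj(), "Bmal")
  expect_true(sc$rhythmic)
  expect_equal(sc$period, base, tolerance = 1e-3)
})

test_that("scans are reproducible and keep the grid order", {
  m <- test_model()
  g <- c(0.7, 1.0)
  a <- ktt_scan(m, "KO", g, onset = 12, out_dt = 0.05)
  b <- ktt_scan(m, "KO", g, onset = 12, out_dt = 0.05)
  expect_identical(a, b)
  expect_identical(a$ktt, g)
  expect_error(ktt_scan(m, "WT", c(0.4, 0.4)), "ktt_grid")
})

test_that("onset scan: identity perturbation is onset-independent and
          onsets one period apart coincide", {
  m <- test_model()
  idsc <- onset_scan(m, "WT", ktt = 1, onset_grid = c(0, 7, 13),
                     out_dt = 0.02)
  expect_lt(diff(range(idsc$period)), 0.01)
  P <- estimate_period_transient(wt_traj(), "Bmal")
  sc <- onset_scan(m, "KO", ktt = 0.7, onset_grid = c(2, 2 + P),
                   out_dt = 0.02)
  expect_lt(abs(diff(sc$period)), 0.02)
})

test_that("control coefficients are finite on a parameter subset and the
          perturbed systems stay rhythmic", {
  m <- test_model()
  cco <- control_coefficients(m, delta = 0.10,
                              parameters = c("v_per", "dm_rev", "kt_bmal",
                                             "ka_ror_cb"),
                              out_dt = 0.05)
  expect_equal(nrow(cco), 4)
  expect_true(all(cco$rhythmic_up & cco$rhythmic_down))
  expect_true(all(is.finite(c(cco$coef_up, cco$coef_down))))
})

test_that("a uniform perturbation of all 1/h-rate parameters realises the
          analytic control coefficient of time rescaling", {
  m <- test_model()
  T0 <- cc_period(m, burn_in = 300, out_dt = 0.02)
  for (f in c(1.1, 0.9)) {
    T1 <- cc_period(cc_rescale_time(m, f), burn_in = 300 / f,
                    horizon = 130 / f, out_dt = 0.02)
    coef <- ((T1 - T0) / T0) / (f - 1)
    expect_equal(coef, (1 / f - 1) / (f - 1), tolerance = 1e-3)
  }
})

test_that("calibration returns already-feasible parameters unchanged", {
  m <- test_model()
  P <- cc_period(m, burn_in = 240, out_dt = 0.02)
  res <- cc_calibrate(m, period = P, out_dt = 0.02)
  expect_true(res$ok)
  expect_equal(res$objective, 0)
  expect_identical(res$model$params, m$params)
})

test_that("calibration meets an off-target period by pure time rescaling", {
  m <- test_model()
  res <- cc_calibrate(m, period = 20, out_dt = 0.02)
  expect_true(res$ok)
  expect_equal(res$period, 20, tolerance = 0.01)
  # thresholds and exponents untouched; 1/h rates scaled by one common factor
  tu <- cc_parameters()$time_unit
  expect_identical(res$model$params[!tu], m$params[!tu])
  ratio <- res$model$params[tu] / m$params[tu]
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("parameter recovery: a +/-5 % disturbance of the rates is
          re-calibrated back to the target period", {
  m <- test_model()
  P <- cc_period(m, burn_in = 240, out_dt = 0.02)
  set.seed(5)
  md <- m
  tu <- which(cc_parameters()$time_unit)
  md$params[tu] <- md$params[tu] * runif(length(tu), 0.95, 1.05)
  res <- cc_calibrate(md, period = P, out_dt = 0.02)
  expect_lt(abs(res$period - P), 0.05)
})

test_that("modular battery covers scenario x genotype x ktt and its ktt = 1
          column equals each scenario's baseline", {
  m <- test_model()
  mb <- modular_analysis_battery(m, ktt_grid = c(0.7, 1.0), onset = 12,
                                 scenarios = c("decouple_m1", "clamp_p53"),
                                 out_dt = 0.05)
  expect_equal(nrow(mb), 2 * 2 * 2)
  expect_setequal(unique(mb$scenario), c("decouple_m1", "clamp_p53"))
  base_dec <- cc_period(m, "WT", list(decouple_module1()), out_dt = 0.05)
  got <- mb$period[mb$scenario == "decouple_m1" & mb$genotype == "WT" &
                   mb$ktt == 1]
  expect_equal(got, base_dec, tolerance = 0.02)
})
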