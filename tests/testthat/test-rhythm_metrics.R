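# Rhythm metrics against analytic and synthetic-generator oracles.

fake_traj <- function(times, ...) {
  # hand-built trajectory carrying only the named series
  cols <- list(...)
  structure(list(times = times,
                 states = do.call(cbind, cols),
                 meta = list()),
            class = "cc_trajectory")
}

test_that("peaks of a pure cosine are found within the grid precision", {
  t <- seq(0, 100, by = 0.01)
  pk <- detect_peaks(t, cos(2 * pi * t / 24))
  expect_equal(pk, c(24, 48, 72, 96), tolerance = 0.01 / 24)
  expect_identical(detect_peaks(t, rep(1.3, length(t))), numeric())
})

test_that("plateaus resolve to their midpoint", {
  t <- seq(0, 10, by = 0.1)
  v <- pmin(1, pmax(0, 1 - abs(t - 5) / 3))  # trapezoid flat on [2, 8]...
  v <- ifelse(t >= 4 & t <= 6, 1, v)         # flat top [4, 6]
  pk <- detect_peaks(t, v)
  expect_equal(pk, 5, tolerance = 0.06)
})

test_that("recovered peak count equals the generator cycle count", {
  spec <- cc_trace_spec(period = 24, amplitude = 1, mesor = 2,
                       damping = 0.004, noise_sd = 0.05, dt = 0.1,
                       duration = 120, phase = -pi / 2, seed = 1)
  tr <- make_trace(spec)
  pk <- detect_peaks(tr$time, tr$value, min_prominence = 0.05)
  # cos(2 pi t/24 - pi/2) peaks at 6, 30, 54, 78, 102 within 120 h
  expect_equal(length(pk), 5)
  expect_equal(pk, c(6, 30, 54, 78, 102), tolerance = 0.05)
})

test_that("transient period statistic: exact cosine, ND fallbacks,
          invariances", {
  t <- seq(0, 150, by = 0.01)
  ser <- data.frame(time = t, value = cos(2 * pi * t / 24))
  expect_equal(estimate_period_transient(ser), 24, tolerance = 1e-4)
  # onset shifts measure later peaks only (peaks at 48, 72, 96, 120 remain)
  expect_equal(estimate_period_transient(ser, onset = 30), 24,
               tolerance = 1e-4)
  # fewer than 4 peaks after onset -> ND
  expect_true(is.na(estimate_period_transient(ser, onset = 80)))
  # constant -> ND
  expect_true(is.na(estimate_period_transient(
    data.frame(time = t, value = rep(1, length(t))))))
  # translation and amplitude-scale invariance
  ser2 <- data.frame(time = t, value = 7.5 * cos(2 * pi * (t - 3.21) / 24))
  expect_equal(estimate_period_transient(ser2),
               estimate_period_transient(ser), tolerance = 1e-6)
})

test_that("CT phase map anchors Bmal at 21 and places other species by
          their peak offset", {
  t <- seq(0, 120, by = 0.01)
  tr <- fake_traj(t,
    Bmal = cos(2 * pi * (t - 5) / 24),
    Rev = cos(2 * pi * (t - 11.8) / 24),   # 6.8 h after Bmal -> CT 3.80
    Flat = rep(1, length(t)))
  ph <- peak_phase_ct(tr, c("Bmal", "Rev", "Flat"))
  expect_equal(unname(ph["Bmal"]), 21, tolerance = 1e-3)
  expect_equal(unname(ph["Rev"]), 3.80, tolerance = 1e-2)
  expect_true(is.na(ph["Flat"]))
})

test_that("pairwise CT phase differences are translation-invariant", {
  t <- seq(0, 120, by = 0.02)
  mk <- function(shift) fake_traj(t,
    Bmal = cos(2 * pi * (t - 5 - shift) / 24),
    Per = cos(2 * pi * (t - 19 - shift) / 24))
  for (shift in c(0, 3.3, 11)) {
    ph <- peak_phase_ct(mk(shift), c("Bmal", "Per"))
    expect_equal(unname((ph["Per"] - ph["Bmal"]) %% 24), 14,
                 tolerance = 1e-2)
  }
})

test_that("cycle mean integrates over whole periods", {
  t <- seq(0, 100, by = 0.01)
  tr <- fake_traj(t, Const = rep(2.7, length(t)),
                  Osc = 5.7 + 1.3 * cos(2 * pi * t / 23.65))
  expect_equal(cycle_mean(tr, "Const"), 2.7)
  # the mesor is recovered although the window is not a whole period count
  expect_equal(cycle_mean(tr, "Osc"), 5.7, tolerance = 1e-3)
})

test_that("cosinor fit recovers exact and noisy parameters", {
  t <- seq(0, 24, by = 3)               # 9 samples at 3-h spacing
  y <- 2 + 1.5 * cos(2 * pi * (t - 7.3) / 24)
  fit <- fit_harmonic(t, y, period = 24)
  expect_equal(fit$mesor, 2, tolerance = 1e-10)
  expect_equal(fit$amplitude, 1.5, tolerance = 1e-10)
  expect_equal(fit$acrophase, 7.3, tolerance = 1e-8)
  # constant series -> amplitude 0
  expect_equal(fit_harmonic(t, rep(4, 9), period = 24)$amplitude, 0)
  # noisy cosinor: amplitude within 3 SE of truth (linear-model SE oracle)
  set.seed(7)
  yn <- 2 + 1 * cos(2 * pi * t / 24) + rnorm(9, 0, 0.2)
  fitn <- fit_harmonic(t, yn, period = 24)
  olm <- lm(yn ~ cos(2 * pi * t / 24) + sin(2 * pi * t / 24))
  b <- coef(olm)[2:3]; V <- vcov(olm)[2:3, 2:3]
  g <- b / sqrt(sum(b^2))               # delta method for the amplitude SE
  se_amp <- sqrt(drop(t(g) %*% V %*% g))
  expect_lt(abs(fitn$amplitude - 1), 3 * se_amp)
  expect_equal(fitn$amplitude, sqrt(sum(b^2)), tolerance = 1e-10)
})

test_that("free-period cosinor recovers the generator period", {
  spec <- cc_trace_spec(period = 25.1, amplitude = 1, mesor = 3,
                        noise_sd = 0, dt = 1, duration = 48)
  tr <- make_trace(spec)
  fit <- fit_harmonic(tr$time, tr$value, period = NULL,
                      period_range = c(20, 30))
  expect_equal(fit$period, 25.1, tolerance = 1e-3)
  expect_equal(fit$amplitude, 1, tolerance = 1e-3)
})

test_that("polynomial fit matches the normal-equations oracle", {
  # exact quartic
  t <- seq(-3, 3, length.out = 15)
  cf_true <- c(0.5, -1, 0.25, 2, -0.125)
  y <- drop(outer(t, 0:4, "^") %*% cf_true)
  expect_equal(fit_polynomial(t, y, 4)$coefficients, cf_true,
               tolerance = 1e-8)
  # constant -> intercept only
  cf0 <- fit_polynomial(t, rep(3.3, 15), 4)$coefficients
  expect_equal(cf0[1], 3.3)
  expect_equal(cf0[-1], rep(0, 4), tolerance = 1e-10)
  # random data against explicit normal equations
  set.seed(11)
  yr <- rnorm(15)
  X <- outer(t, 0:4, "^")
  oracle <- drop(solve(t(X) %*% X, t(X) %*% yr))
  expect_equal(fit_polynomial(t, yr, 4)$coefficients, oracle,
               tolerance = 1e-6)
  expect_error(fit_polynomial(t[1:4], yr[1:4], 4), "length")
})

test_that("rhythm summary mirrors the ND convention", {
  t <- seq(0, 120, by = 0.02)
  tr <- fake_traj(t, Bmal = cos(2 * pi * t / 24), Flat = rep(1, length(t)))
  s <- rhythm_summary(tr, c("Bmal", "Flat"))
  expect_true(s$rhythmic[s$species == "Bmal"])
  expect_false(s$rhythmic[s$species == "Flat"])
  expect_true(is.na(s$period[s$species == "Flat"]))   # ND
  expect_true(is.na(s$phase_ct[s$species == "Flat"]))
})
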