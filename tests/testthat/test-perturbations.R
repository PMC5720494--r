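# Intervention algebra: construction, validation, composition, contracts.

test_that("perturbation specs validate their magnitudes", {
  expect_error(apply_ras(0), "ktt")
  expect_error(apply_ras(-0.5), "ktt")
  expect_error(cc_perturbation("ras_ktt", onset = -1, magnitude = 1), "onset")
  expect_error(knockdown_bmal1(0), "fraction")
  expect_error(knockdown_bmal1(1.2), "fraction")
  expect_error(clamp_species("NotASpecies", 1), "species")
  expect_error(clamp_species("E2F_N", -2), "clamp level")
  expect_s3_class(apply_ras(0.4), "cc_perturbation")
})

test_that("neutral magnitudes are the identity on trajectories", {
  m <- test_model()
  base <- cc_run_scenario(m, "WT", horizon = 40, burn_in = 60, out_dt = 0.1)
  ras1 <- cc_run_scenario(m, "WT", list(apply_ras(1)), horizon = 40,
                          burn_in = 60, out_dt = 0.1)
  kd1 <- cc_run_scenario(m, "WT", list(knockdown_bmal1(1)), horizon = 40,
                         burn_in = 60, out_dt = 0.1)
  expect_identical(base$states, ras1$states)
  expect_identical(base$states, kd1$states)
})

test_that("perturbations are idempotent and order-independent", {
  m <- test_model()
  run <- function(perts) cc_run_scenario(m, "WT", perts, horizon = 30,
                                         burn_in = 50, out_dt = 0.1)$states
  once <- run(list(apply_ras(0.6), knockout_ink4a_arf()))
  twice <- run(list(apply_ras(0.6), knockout_ink4a_arf(),
                    knockout_ink4a_arf()))
  swapped <- run(list(knockout_ink4a_arf(), apply_ras(0.6)))
  expect_identical(once, twice)
  expect_identical(once, swapped)
})

test_that("knockout zeroes the six Ink4a/Arf species for all time", {
  traj <- ko_traj()
  ko6 <- cc_equation_species(c(1, 2, 8, 10, 14, 19))
  expect_identical(max(abs(traj$states[, ko6])), 0)
  # everything else still moves
  expect_gt(min(apply(traj$states[, c("Bmal", "Per", "CB")], 2,
                      function(v) diff(range(v)))), 0)
})

test_that("module decoupling zeroes exactly the documented species", {
  m <- test_model()
  t1 <- cc_run_scenario(m, "WT", list(decouple_module1()), horizon = 60,
                        burn_in = 100, out_dt = 0.1)
  expect_identical(max(abs(t1$states[, cc_equation_species(c(7, 12, 22))])), 0)
  t2 <- cc_run_scenario(m, "WT", list(decouple_module2()), horizon = 60,
                        burn_in = 100, out_dt = 0.1)
  expect_identical(max(abs(t2$states[, "p53_N"])), 0)
  expect_gt(diff(range(t2$states[, "p53"])), 0)  # mRNA keeps cycling
})

test_that("clamping holds the species at the level to machine precision
          and clamp(., 0) equals decoupling", {
  m <- test_model()
  cl <- cc_run_scenario(m, "WT", list(clamp_species("E2F_N", 5.7)),
                        horizon = 60, burn_in = 100, out_dt = 0.1)
  expect_identical(range(cl$states[, "E2F_N"]), c(5.7, 5.7))
  z1 <- cc_run_scenario(m, "WT", list(clamp_species("p53_N", 0)),
                        horizon = 40, burn_in = 60, out_dt = 0.1)
  z2 <- cc_run_scenario(m, "WT", list(decouple_module2()),
                        horizon = 40, burn_in = 60, out_dt = 0.1)
  expect_identical(z1$states[, "p53_N"], z2$states[, "p53_N"])
  expect_equal(z1$states, z2$states)
})

test_that("Bmal1 knockdown scales Bmal expression and kills rhythmicity
          at strong knockdown", {
  m <- test_model()
  wt <- cc_run_scenario(m, "WT", horizon = 120, burn_in = 240, out_dt = 0.05)
  kd <- cc_run_scenario(m, "WT", list(knockdown_bmal1(0.3)), horizon = 120,
                        burn_in = 240, out_dt = 0.05)
  ratio <- cycle_mean(kd, "Bmal") / cycle_mean(wt, "Bmal")
  # transcription is scaled by 0.3, but the realised mRNA ratio sits well
  # above it: the weakened clock relieves REV-ERB repression of Bmal, which
  # partially compensates (see the methods vignette).  Assert the
  # downregulation and its monotonicity rather than a fixed ratio.
  expect_lt(ratio, 0.8)
  expect_gt(ratio, 0.1)
  milder <- cc_run_scenario(m, "WT", list(knockdown_bmal1(0.6)),
                            horizon = 120, burn_in = 240, out_dt = 0.05)
  ratio2 <- cycle_mean(milder, "Bmal") / cycle_mean(wt, "Bmal")
  expect_gt(ratio2, ratio)
  expect_lt(ratio2, 1)
  hard <- cc_run_scenario(m, "WT", list(knockdown_bmal1(0.02)),
                          horizon = 120, burn_in = 240, out_dt = 0.05)
  expect_false(is_rhythmic(hard, "Bmal"))
  expect_true(is.na(estimate_period_transient(hard, "Bmal")))
})

test_that("onset scheduling leaves the system unperturbed before onset", {
  m <- test_model()
  base <- cc_run_scenario(m, "WT", horizon = 60, burn_in = 100, out_dt = 0.1)
  late <- cc_run_scenario(m, "WT", list(apply_ras(0.4, onset = 30)),
                          horizon = 60, burn_in = 100, out_dt = 0.1)
  pre <- late$times <= 30
  expect_equal(late$states[pre, ], base$states[pre, ], tolerance = 1e-8)
  post <- late$times > 35
  expect_gt(max(abs(late$states[post, "Per"] - base$states[post, "Per"])), 1e-3)
})
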