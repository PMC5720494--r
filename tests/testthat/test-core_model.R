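# Core model: kinetic primitives, censuses, right-hand-side contracts.

test_that("hill kinetics match direct arithmetic and obey complementarity", {
  # symmetry point and limits
  expect_equal(hill_activation(1, 1, 3), 0.5)
  expect_equal(hill_activation(5, 5, 7.3), 0.5)
  expect_equal(hill_activation(0, 2, 4), 0)
  expect_equal(hill_inhibition(0, 2, 4), 1)
  expect_equal(hill_inhibition(3, 3, 2), 0.5)
  # direct arithmetic oracle
  expect_equal(hill_activation(2, 1, 4), 16 / 17)
  # complementarity identity on a deterministic grid of cases
  xs <- c(0, 0.1, 0.7, 1, 2.5, 40)
  for (k in c(0.3, 1, 6)) for (n in c(1, 2.7, 5))
    expect_equal(hill_activation(xs, k, n) + hill_inhibition(xs, k, n),
                 rep(1, length(xs)))
  # monotonicity in x
  expect_true(all(diff(hill_activation(seq(0, 10, by = 0.1), 2, 3)) > 0))
  # parameter errors
  expect_error(hill_activation(1, 0, 2), "k")
  expect_error(hill_activation(1, 1, -1), "n")
  expect_error(hill_activation(-1, 1, 2), "x")
})

test_that("species and parameter censuses are exact", {
  sp <- cc_species()
  expect_equal(nrow(sp), 46)
  expect_equal(sum(!is.na(sp$equation)), 45)
  expect_false(any(duplicated(sp$name)))
  expect_true(all(sp$role %in% c("mRNA", "protein_cytoplasm",
                                 "protein_nucleus", "complex")))
  pa <- cc_parameters()
  expect_equal(nrow(pa), 170)
  expect_false(any(duplicated(pa$name)))
  m <- cc_model()
  expect_identical(names(m$params), pa$name)
  expect_true(all(m$params >= 0))
  expect_equal(m$ktt, 1)
})

test_that("published equation indices map to the documented species", {
  expect_identical(cc_equation_species(c(1, 2, 8, 10, 14, 19)),
                   c("Ink4a", "Arf", "INK4A_C", "ARF_C", "INK4A_N", "ARF_N"))
  expect_identical(cc_equation_species(c(7, 12, 22)),
                   c("E2f", "E2F_C", "E2F_N"))
  expect_identical(cc_equation_species(16), "p53_N")
  expect_error(cc_equation_species(46))
})

test_that("every species is referenced by the rate equations", {
  # a dynamic species is referenced iff perturbing it changes some
  # derivative; RB1p_N is the conserved remainder of the RB1 pool, so its
  # influence enters through the conservation law instead
  m <- test_model()
  y <- setNames(rep(1, 46), cc_species()$name)
  base <- cc_rhs(0, y, m)
  for (sp in setdiff(cc_species()$name, "RB1p_N")) {
    y2 <- y
    y2[sp] <- 1.37
    touched <- any(abs(cc_rhs(0, y2, m) - base) > 0)
    expect_true(touched, info = sp)
  }
  # the conserved pool: moving RB1_N moves the reported RB1p_N derivative
  y2 <- y; y2["RB1_N"] <- 1.37
  expect_false(cc_rhs(0, y2, m)[["RB1p_N"]] == base[["RB1p_N"]])
})

test_that("rhs agrees with a central finite difference along a trajectory", {
  m <- test_model()
  traj <- wt_traj()
  h <- 0.02  # the output grid spacing
  idx <- c(500, 1500, 3000, 5000)
  for (i in idx) {
    fd <- (traj$states[i + 1, ] - traj$states[i - 1, ]) / (2 * h)
    an <- cc_rhs(traj$times[i], pmax(traj$states[i, ], 0), m)
    # second-order finite difference: tolerance scales with curvature
    expect_lt(max(abs(fd - an)) / max(abs(an), 1), 5e-3)
  }
})

test_that("rhs flags non-finite states with the offending species", {
  m <- test_model()
  y <- setNames(rep(1, 46), cc_species()$name)
  y["p53_N"] <- NaN
  expect_error(cc_rhs(0, y, m), "p53_N")
})

test_that("knockout and clamp contexts zero exactly the right derivatives", {
  m <- test_model()
  y <- setNames(runif(46, 0.5, 2), cc_species()$name)
  ko6 <- c("Ink4a", "Arf", "INK4A_C", "ARF_C", "INK4A_N", "ARF_N")
  y[ko6] <- 0
  ctx <- cc_context(frozen = ko6, values = setNames(rep(0, 6), ko6))
  d <- cc_rhs(0, y, m, ctx)
  expect_identical(unname(d[ko6]), rep(0, 6))
  expect_true(all(abs(d[setdiff(names(d), c(ko6, "RB1p_N"))]) > 0))
  # single-species clamp
  ctx2 <- cc_context(frozen = "E2F_N", values = c(E2F_N = 5.7))
  d2 <- cc_rhs(0, y, m, ctx2)
  expect_identical(unname(d2["E2F_N"]), 0)
})

test_that("ktt = 1 is bit-identical to the unperturbed vector field", {
  m <- test_model()
  y <- setNames(runif(46, 0.2, 3), cc_species()$name)
  expect_identical(cc_rhs(0, y, m, cc_context(ktt = 1)),
                   cc_rhs(0, y, m, NULL))
})

test_that("interaction wiring reproduces the published network links", {
  iw <- cc_interactions()
  has <- function(src, tgt, sgn) any(iw$source == src & iw$target == tgt &
                                     iw$sign == sgn)
  expect_true(has("CB", "Wee1", "activation"))
  expect_true(has("CB", "Myc", "inhibition"))
  expect_true(has("MYC_N", "CB", "inhibition"))       # competitive E-box binding
  expect_true(has("PERCRY_N", "Ink4a", "activation"))
  expect_true(has("INK4A_N", "CDC_N", "inhibition"))
  expect_true(has("CDC_N", "RB1_N", "inhibition"))    # phosphorylation
  expect_true(has("RB1_N", "E2F_N", "inhibition"))
  expect_true(has("E2F_N", "Bmal", "activation"))     # MotifMap-predicted link
  expect_true(has("MYC_N", "Arf", "activation"))
  expect_true(has("ARF_N", "MDM2_N", "inhibition"))
  expect_true(has("MDM2_N", "p53_N", "inhibition"))
  expect_true(has("p53_N", "Mdm2", "activation"))
  expect_true(has("p53_N", "Per", "inhibition"))
  # ktt scales exactly the CLOCK/BMAL-mediated transcription terms
  expect_setequal(iw$target[iw$ktt_scaled],
                  c("Per", "Cry", "Rev", "Ror", "Wee1", "Myc"))
})

test_that("model config round-trips and censuses are validated on load", {
  m <- cc_model()
  tmp <- tempfile(fileext = ".yaml")
  cc_save_model(m, tmp)
  m2 <- cc_load_model(tmp)
  expect_equal(m2$params, m$params)
  expect_equal(m2$init, m$init)
  # corrupt the file: drop a parameter
  cfg <- yaml::read_yaml(tmp)
  cfg$parameters$v_per <- NULL
  yaml::write_yaml(cfg, tmp)
  expect_error(cc_load_model(tmp), "parameter census")
})

test_that("edge-list export writes a readable TSV", {
  tmp <- tempfile(fileext = ".tsv")
  cc_write_edgelist(tmp)
  el <- read.delim(tmp)
  expect_equal(nrow(el), nrow(cc_interactions()))
  expect_true(all(el$source %in% cc_species()$name))
})
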