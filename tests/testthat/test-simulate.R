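test_that("a flux-free system stays constant and an empty one stays dark", {
  mech <- default_mechanism(constants = list(k_init = 0))
  # no radicals present and no initiation: nothing can move
  co <- simulate_course(mech, default_initial_state(), seq(0, 120, 4))
  for (sp in colnames(co$concentrations)) {
    expect_equal(unname(co$concentrations[, sp]),
                 rep(unname(co$concentrations[1, sp]),
                     nrow(co$concentrations)),
                 tolerance = 1e-10)
  }
  # no substrate: no chromophore can ever form
  co0 <- simulate_course(default_mechanism(),
                         initial_state(c(EPI = 0, O2 = 2.51e-4)),
                         seq(0, 300, 4))
  expect_true(all(abs(co0$absorbance_347) < 1e-12))
})

test_that("simulation rejects bad inputs with clear errors", {
  mech <- default_mechanism()
  expect_error(initial_state(c(EPI = -1e-5)), "negative")
  expect_error(simulate_course(mech, default_initial_state(),
                               c(0, 2, 2, 4)), "strictly increasing")
  expect_error(simulate_course(mech, default_initial_state(),
                               c(5, 10)), "start at 0")
  expect_error(simulate_course(mech, initial_state(c(AO = 1e-6)),
                               seq(0, 10, 2)), "absent")
})

test_that("skeleton totals are conserved and concentrations stay non-negative", {
  co <- control_course()
  tot <- skeleton_totals(co, substrate_ids)
  expect_true(all(abs(tot / tot[1] - 1) < 10 * co$rtol))
  expect_true(all(co$concentrations > -10 * co$atol))
  # with antioxidant: both skeletons conserved at a mid-curve dose
  m2 <- default_mechanism(TRUE)
  co2 <- simulate_course(m2, default_initial_state(ao = 2e-5),
                         seq(0, 600, 5))
  s2 <- skeleton_totals(co2, substrate_ids)
  a2 <- skeleton_totals(co2, antioxidant_ids)
  expect_true(all(abs(s2 / s2[1] - 1) < 10 * co2$rtol))
  expect_true(all(abs(a2 / a2[1] - 1) < 10 * co2$rtol))
  expect_true(all(co2$concentrations > -10 * co2$atol))
})

test_that("closed-cuvette oxygen consumption is 1-3 molecules per substrate", {
  co <- control_course()
  n <- length(co$times)
  o2_used <- co$concentrations[1, "O2"] - co$concentrations[n, "O2"]
  epi_used <- co$concentrations[1, "EPI"] - co$concentrations[n, "EPI"]
  ratio <- o2_used / epi_used
  expect_gte(ratio, 1)
  expect_lte(ratio, 3)
})

test_that("clamped oxygen mode holds O2 at its initial value", {
  mech <- default_mechanism(oxygen_mode = "clamped")
  co <- simulate_course(mech, default_initial_state(), seq(0, 300, 5))
  expect_equal(co$concentrations[, "O2"],
               rep(2.51e-4, nrow(co$concentrations)), tolerance = 1e-10)
})

test_that("the 3-min absorbance increase is non-decreasing in pH over 9-11", {
  dd <- vapply(seq(9, 11, by = 0.5), function(ph) {
    mech <- default_mechanism(pH = ph)
    co <- simulate_course(mech, default_initial_state(), seq(0, 200, 4))
    delta_d(course_to_trace(co), 180)
  }, numeric(1))
  expect_true(all(diff(dd) >= 0))
})

test_that("reduced clamped-oxygen network matches the closed-form oracle", {
  times <- seq(0, 60, 1)
  mech <- reduced_mechanism()
  co <- simulate_course(mech,
                        initial_state(c(EPI = 2.6e-4, O2 = 2.51e-4)),
                        times)
  oracle <- reduced_oracle(times)
  # compare where the product has grown clear of the absolute tolerance
  keep <- oracle$Q > 1e-10
  expect_gt(sum(keep), 30)
  rel_q <- abs(co$concentrations[keep, "Q"] - oracle$Q[keep]) /
    oracle$Q[keep]
  expect_lt(max(rel_q), 0.01)
  keep_u <- oracle$SUP > 1e-12
  rel_u <- abs(co$concentrations[keep_u, "SUP"] - oracle$SUP[keep_u]) /
    oracle$SUP[keep_u]
  expect_lt(max(rel_u), 0.01)
})

test_that("kinetic chain length behaves like a propagation/initiation ratio", {
  co <- control_course()
  nu <- kinetic_chain_length(co, window = c(0, 180))
  expect_gte(nu, 10)  # long chains: tens of links
  # no propagation: chain length collapses to zero
  m0 <- default_mechanism(constants = list(
    k_prop_sub_sup = 0, k_prop_sq_o2 = 0, k_prop_lac_sup = 0,
    k_prop_asq_o2 = 0))
  co0 <- simulate_course(m0, default_initial_state(), seq(0, 200, 4))
  expect_equal(kinetic_chain_length(co0, window = c(0, 180)), 0)
  # doubling both substrate propagation constants cannot shorten the chain
  m2 <- default_mechanism(constants = list(k_prop_sub_sup = 2e4,
                                           k_prop_sq_o2 = 2e5))
  co2 <- simulate_course(m2, default_initial_state(), seq(0, 200, 4))
  expect_gte(kinetic_chain_length(co2, window = c(0, 180)), nu)
  # zero initiation flux is flagged as an infinite chain
  mi <- default_mechanism(constants = list(k_init = 0))
  coi <- simulate_course(mi, default_initial_state(), seq(0, 200, 4))
  expect_warning(nu_inf <- kinetic_chain_length(coi, window = c(0, 180)),
                 "infinite")
  expect_identical(nu_inf, Inf)
})

test_that("dose-response of the calibrated antioxidant mechanism is U-shaped", {
  mech <- default_mechanism(antioxidant_present = TRUE)
  curve <- dose_response(mech, 10^seq(log10(1e-7), log10(1e-4),
                                      length.out = 9))
  curve <- characterize_u_shape(curve, noise_margin = 0)
  expect_true(curve$is_u_shaped)
  i <- which.min(curve$responses)
  expect_gt(i, 1)
  expect_lt(i, length(curve$doses))
})
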