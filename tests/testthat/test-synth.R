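test_that("generation is deterministic given the seed", {
  design <- experiment_design(control_replicates = 1,
                              ao_doses = c(1.5e-6), dose_replicates = 2,
                              duration_s = 120, sample_interval_s = 4)
  mech <- default_mechanism(TRUE)
  d1 <- generate_kinetic_dataset(design, mech, noise_model(seed = 3))
  d2 <- generate_kinetic_dataset(design, mech, noise_model(seed = 3))
  d3 <- generate_kinetic_dataset(design, mech, noise_model(seed = 4))
  expect_identical(lapply(d1, `[[`, "absorbance"),
                   lapply(d2, `[[`, "absorbance"))
  expect_false(identical(d1[[1]]$absorbance, d3[[1]]$absorbance))
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99)
  invisible(generate_kinetic_dataset(design, mech, noise_model(seed = 3)))
  expect_identical(rnorm(3), before)
})

test_that("a noiseless zero-dose trace equals the mechanism simulation", {
  design <- experiment_design(control_replicates = 1,
                              ao_doses = numeric(0),
                              include_blanks = FALSE,
                              duration_s = 200, sample_interval_s = 4)
  mech <- default_mechanism()
  ds <- generate_kinetic_dataset(design, mech,
                                 noise_model(sd_absorbance = 0, seed = 1))
  course <- simulate_course(mech, default_initial_state(),
                            seq(0, 200, 4))
  expect_equal(ds[[1]]$absorbance, course$absorbance_347)
  expect_true(ds[[1]]$contains_substrate)
})

test_that("blank traces carry only drift and noise", {
  design <- experiment_design(control_replicates = 1,
                              ao_doses = numeric(0),
                              include_blanks = TRUE,
                              duration_s = 400, sample_interval_s = 2)
  mech <- default_mechanism()
  drift <- 1e-5
  dds <- vapply(1:12, function(s) {
    ds <- generate_kinetic_dataset(
      design, mech, noise_model(0.005, baseline_drift_per_s = drift,
                                seed = s))
    blanks <- Filter(function(tr) !tr$contains_substrate, ds)
    expect_length(blanks, 1)
    delta_d(blanks[[1]], 180)
  }, numeric(1))
  centre <- drift * 180
  se <- sd(dds) / sqrt(length(dds))
  expect_lt(abs(mean(dds) - centre), 4 * se)
  # spread is set by the endpoint noise, sqrt(2) * sd
  expect_gt(sd(dds), 0.002)
  expect_lt(sd(dds), 0.02)
})

test_that("the end-to-end noisy pipeline detects the U shape and a sane AOA", {
  # dose grid spanning the calibrated optimum (~2e-5 M), replication
  # chosen by power analysis: the rising branch is ~0.009 AU, so 24
  # replicates put the default noise margin (2 * pooled SD / sqrt(n))
  # near 0.003 AU and the comparison has >99% power
  design <- experiment_design(control_replicates = 6,
                              ao_doses = c(1, 5, 20, 100) * 1e-6,
                              dose_replicates = 24)
  mech <- default_mechanism(TRUE)
  ds <- generate_kinetic_dataset(design, mech, noise_model(seed = 101))
  res <- analyze_dataset(ds)
  curve <- characterize_u_shape(res$curve)
  expect_true(curve$is_u_shaped)
  expect_equal(curve$minimum_dose, 2e-5)
  aoa <- aoa_modified(curve, res$delta_ctrl)$aoa_percent
  expect_gt(aoa, 0)
  expect_lt(aoa, 100)
})

test_that("pointwise blank correction is available for synthetic data", {
  design <- experiment_design(control_replicates = 2,
                              ao_doses = numeric(0),
                              include_blanks = TRUE,
                              duration_s = 300, sample_interval_s = 4)
  ds <- generate_kinetic_dataset(design, default_mechanism(),
                                 noise_model(0.002, 2e-5, seed = 9))
  scalar <- analyze_dataset(ds, blank_mode = "scalar")
  pointwise <- analyze_dataset(ds, blank_mode = "pointwise")
  # both remove the drift to within the noise scale
  expect_equal(scalar$delta_ctrl, pointwise$delta_ctrl, tolerance = 0.05)
})

test_that("initiation constant is recovered from synthetic control traces", {
  mech <- default_mechanism()
  k_true <- default_rate_constants()$k_init
  course <- control_course()
  tr <- course_to_trace(course)
  k_hat <- recover_initiation(tr, mech)
  expect_equal(as.numeric(k_hat), k_true, tolerance = 0.01)
})

test_that("DPPH generation round-trips exactly without noise", {
  truth <- c(0, 30, 86, 150)
  recs <- generate_dpph_dataset(truth, noise_model(sd_absorbance = 0,
                                                   seed = 1))
  got <- vapply(recs, function(r) {
    suppressWarnings(antioxidant_concentration(r)$cao_mg_l)
  }, numeric(1))
  expect_equal(got, truth, tolerance = 1e-10)
  # truths implying > 100% conversion are rejected with advice
  expect_error(generate_dpph_dataset(1e5, noise_model(seed = 1)),
               "smaller extract volume")
  # zero truth: test absorbance scatters around the blank
  z <- generate_dpph_dataset(rep(0, 40), noise_model(seed = 2))
  d <- vapply(z, function(r) r$d_exp - r$d_blank, numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1e-3)
})

test_that("noisy DPPH quantitation recovers the truth within 2 standard errors", {
  truth <- 86
  recs <- generate_dpph_dataset(rep(truth, 50),
                                noise_model(0.005, seed = 5))
  got <- vapply(recs, function(r) {
    suppressWarnings(antioxidant_concentration(r)$cao_mg_l)
  }, numeric(1))
  se <- sd(got) / sqrt(length(got))
  expect_lt(abs(mean(got) - truth), 2 * se)
})
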