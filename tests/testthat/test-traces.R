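test_that("windowed absorbance increase handles flat, linear and short traces", {
  t <- seq(0, 240, 2)
  expect_equal(delta_d(kinetic_trace(t, rep(0.2, length(t)))), 0)
  expect_equal(delta_d(kinetic_trace(t, 0.002 * t), 180), 0.36)
  # window end between samples: linear interpolation
  tr <- kinetic_trace(c(0, 100, 250), c(0, 0.1, 0.25))
  expect_equal(delta_d(tr, 180), 0.18)
  expect_error(delta_d(kinetic_trace(seq(0, 100, 2), seq(0, 1, 0.02)),
                       180), "short")
})

test_that("blank correction reproduces the tabulated assay rows", {
  # yarrow extract volumes (system, blank, printed corrected value)
  yarrow <- rbind(c(0.230, 0.025, 0.204),   # printed from pre-rounded inputs
                  c(0.146, -0.002, 0.148),
                  c(0.172, 0.002, 0.170),
                  c(0.188, -0.001, 0.189))
  chloro <- rbind(c(0.311, -0.001, 0.312),
                  c(0.301, -0.002, 0.303),
                  c(0.351, -0.003, 0.354),
                  c(0.357, -0.015, 0.372),
                  c(0.367, -0.040, 0.407))
  rows <- rbind(yarrow, chloro)
  got <- blank_correct(rows[, 1], rows[, 2])
  expect_true(all(abs(got - rows[, 3]) <= 0.001 + 1e-12))
  expect_equal(blank_correct(0.146, -0.002), 0.148)
  expect_equal(blank_correct(0.42, 0), 0.42)
})

test_that("initial rate is exact on linear traces and reports a sane error", {
  t <- seq(0, 100, 2)
  tr <- kinetic_trace(t, 1e-3 * t)
  r <- initial_rate(tr, epsilon = 1000)
  expect_equal(as.numeric(r), 1e-6, tolerance = 1e-12)
  expect_lt(attr(r, "std_error"), 1e-15)
  expect_equal(as.numeric(initial_rate(kinetic_trace(t, rep(0.3, 51)),
                                       epsilon = 1000)), 0)
  expect_error(initial_rate(tr, epsilon = 0), "positive")
  expect_error(initial_rate(kinetic_trace(c(0, 50, 100), c(0, 1, 2)),
                            epsilon = 1, fit_window_s = 60), "3 samples")
  # standard error scales like 1/sqrt(n) for denser sampling of a window
  tr1 <- kinetic_trace(seq(0, 60, 2), rep(0.1, 31))
  tr2 <- kinetic_trace(seq(0, 60, 0.2), rep(0.1, 301))
  set.seed(7)
  se1 <- mean(replicate(40, {
    a <- tr1$absorbance + rnorm(31, 0, 0.005)
    attr(initial_rate(kinetic_trace(tr1$times, a), 1000), "std_error")
  }))
  se2 <- mean(replicate(40, {
    a <- tr2$absorbance + rnorm(301, 0, 0.005)
    attr(initial_rate(kinetic_trace(tr2$times, a), 1000), "std_error")
  }))
  expect_equal(se1 / se2, sqrt(301 / 31), tolerance = 0.15)
})

test_that("observed rate constant follows the mass-action quotient", {
  k <- observed_rate_constant(8.7e-7, 2.6e-4, 2.51e-4)
  expect_equal(k, 13.33, tolerance = 1e-3)
  expect_equal(observed_rate_constant(0, 1e-3, 1e-3), 0)
  expect_equal(observed_rate_constant(1e-6, 1e-3, 2.5e-4), 4.0)
  expect_error(observed_rate_constant(1e-6, 0, 1e-3), "positive")
})

test_that("pointwise activity index covers suppression and prooxidation", {
  expect_equal(aoa_pointwise(0.2, 0.2), 0)
  expect_equal(aoa_pointwise(0, 0.37), 100)
  expect_equal(aoa_pointwise(0.407, 0.371), -9.7, tolerance = 0.01)
  expect_error(aoa_pointwise(0.1, 0), "positive")
  # ratio statistic: invariant under uniform absorbance rescaling
  d_exp <- c(0.1, 0.25, 0.4)
  expect_equal(aoa_pointwise(3.7 * d_exp, 3.7 * 0.31),
               aoa_pointwise(d_exp, 0.31))
})

test_that("minimum-based activity reproduces the extract worked examples", {
  curves <- list(
    yarrow = list(ctrl = 0.411, resp = c(0.204, 0.148, 0.170, 0.189),
                  aoa = 64.0),
    camomile = list(ctrl = 0.381, resp = c(0.36, 0.318, 0.33), aoa = 16.5),
    ticks = list(ctrl = 0.356, resp = c(0.34, 0.323, 0.35), aoa = 9.3)
  )
  for (cs in curves) {
    curve <- concentration_response(seq_along(cs$resp), cs$resp,
                                    dose_unit = "uL")
    res <- aoa_modified(curve, cs$ctrl)
    expect_equal(res$aoa_percent, cs$aoa, tolerance = 0.1 / cs$aoa)
    expect_equal(res$delta_min, min(cs$resp))
  }
  # single-point grid: reduces exactly to the pointwise formula
  one <- concentration_response(1.5e-6, 0.303)
  expect_equal(aoa_modified(one, 0.371)$aoa_percent,
               aoa_pointwise(0.303, 0.371))
  expect_identical(aoa_modified(one, 0.371)$formula, "eq_pointwise")
  # scale invariance carries over to the minimum-based index
  big <- concentration_response(1:4, c(0.4, 0.2, 0.3, 0.5))
  expect_equal(aoa_modified(big, 0.45)$aoa_percent,
               aoa_modified(concentration_response(1:4, 2 * big$responses),
                            0.9)$aoa_percent)
})

test_that("U-shape characterization finds the chlorogenic-acid optimum", {
  curve <- concentration_response(c(0.75, 1.5, 7.5, 15, 37.5) * 1e-6,
                                  c(0.312, 0.303, 0.354, 0.372, 0.407))
  # tabulated replicate means: strict neighbour comparison
  curve <- characterize_u_shape(curve, noise_margin = 0)
  expect_true(curve$is_u_shaped)
  expect_equal(curve$minimum_dose, 1.5e-6)
})

test_that("monotone dose-responses are not flagged as U-shaped", {
  up <- characterize_u_shape(
    concentration_response(1:5, c(0.30, 0.32, 0.35, 0.38, 0.41)))
  expect_false(up$is_u_shaped)
  expect_equal(up$minimum_dose, 1)
  down <- characterize_u_shape(
    concentration_response(1:5, c(0.41, 0.38, 0.35, 0.32, 0.30)))
  expect_false(down$is_u_shaped)
  expect_equal(down$minimum_dose, 5)  # most inhibition at the top dose
  # a dip shallower than the noise margin is not a U
  shallow <- characterize_u_shape(
    concentration_response(1:3, c(0.305, 0.300, 0.304)),
    noise_margin = 0.01)
  expect_false(shallow$is_u_shaped)
})

test_that("U-shape minimum agrees with an exhaustive scan on random grids", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:9, 1)
    doses <- sort(runif(n, 1e-7, 1e-4))
    while (any(diff(doses) <= 0)) doses <- sort(runif(n, 1e-7, 1e-4))
    resp <- runif(n, 0.1, 0.45)
    curve <- characterize_u_shape(concentration_response(doses, resp),
                                  noise_margin = 0)
    i_min <- which(resp == min(resp))[1]  # oracle: direct scan
    expect_equal(curve$minimum_dose, doses[i_min])
    expect_identical(curve$is_u_shaped,
                     i_min > 1 && i_min < n &&
                       resp[i_min - 1] > resp[i_min] &&
                       resp[i_min + 1] > resp[i_min])
  }
})
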