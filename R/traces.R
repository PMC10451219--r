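# Statistics computed from absorbance kinetic traces: the three-minute
# absorbance increase, blank correction, initial rate, observed rate
# constant, antioxidant activity indices, and characterization of the
# U-shaped dose-response.

#' A kinetic absorbance trace
#'
#' @param times Sampling times in seconds, strictly increasing.
#' @param absorbance Absorbance readings (AU), same length as `times`.
#' @param wavelength_nm Analytical wavelength (default 347 nm).
#' @param label Free-text label.
#' @param contains_substrate `FALSE` for "no-adrenaline" blank runs.
#' @return Object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, absorbance, wavelength_nm = 347,
                          label = "", contains_substrate = TRUE) {
  stopifnot(is.numeric(times), is.numeric(absorbance))
  if (length(times) != length(absorbance) || length(times) < 2L) {
    stop("times and absorbance must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(times = times, absorbance = absorbance,
         wavelength_nm = wavelength_nm, label = label,
         contains_substrate = isTRUE(contains_substrate)),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace '%s' at %g nm: %d samples over %.0f s%s\n",
              x$label, x$wavelength_nm, length(x$times), max(x$times),
              if (x$contains_substrate) "" else " (blank, no substrate)"))
  invisible(x)
}

#' @export
plot.kinetic_trace <- function(x, ...) {
  plot(x$times, x$absorbance, type = "l", xlab = "time (s)",
       ylab = sprintf("A%g (AU)", x$wavelength_nm), ...)
  invisible(x)
}

#' Extract the 347-nm trace of a simulated course
#'
#' @param course An `autox_course`.
#' @param label Label for the trace.
#' @return A [kinetic_trace()].
#' @export
course_to_trace <- function(course, label = "simulated") {
  stopifnot(inherits(course, "autox_course"))
  kinetic_trace(course$times, course$absorbance_347, 347, label,
                contains_substrate =
                  isTRUE(course$init$concentrations["EPI"] > 0))
}

#' Absorbance increase over a window
#'
#' The assay's primary statistic: absorbance at the end of the window minus
#' absorbance at time zero, with linear interpolation when the window end
#' falls between samples.  The conventional window is the first 3 min of
#' the reaction, during which the difference between inhibited and control
#' runs is largest while the substrate is still far from exhausted.
#'
#' @param trace A [kinetic_trace()].
#' @param window_s Window length in seconds (default 180).
#' @return Absorbance increase in AU.
#' @examples
#' tr <- kinetic_trace(0:200, 0.002 * (0:200))
#' delta_d(tr)  # 0.36
#' @export
delta_d <- function(trace, window_s = 180) {
  stopifnot(inherits(trace, "kinetic_trace"), window_s > 0)
  t_end <- trace$times[1] + window_s
  span <- max(trace$times) - trace$times[1]
  if (span < window_s) {
    stop(sprintf(
      "trace '%s' spans %.1f s but the window needs %.1f s (%.1f s short)",
      trace$label, span, window_s, window_s - span), call. = FALSE)
  }
  a_end <- stats::approx(trace$times, trace$absorbance, xout = t_end)$y
  a_end - trace$absorbance[1]
}

#' Blank correction of an absorbance increase
#'
#' Subtracts the absorbance change of the paired "no-adrenaline" system
#' (buffer plus test sample only) from that of the complete reaction
#' system, isolating the product-formation signal from any absorbance
#' drift of the test sample itself.
#'
#' @param d_system Absorbance increase of the complete system, AU.
#' @param d_blank Absorbance increase of the no-substrate blank, AU.
#' @return `d_system - d_blank`, AU.
#' @examples
#' blank_correct(0.146, -0.002)  # 0.148
#' @export
blank_correct <- function(d_system, d_blank) {
  d_system - d_blank
}

#' Initial reaction rate from a trace
#'
#' Least-squares slope of absorbance against time over the initial fit
#' window, converted to a molar product-formation rate through the
#' Beer-Lambert factor `epsilon * pathlength`.
#'
#' @param trace A [kinetic_trace()].
#' @param epsilon Molar absorptivity of the reporting chromophore at the
#'   trace wavelength, per M per cm.  Must be positive.
#' @param pathlength_cm Cuvette path length, cm.
#' @param fit_window_s Fit window from the start of the trace, seconds.
#'   At least 3 samples must fall inside it.
#' @return Rate in M/s, with attributes `std_error` (standard error of the
#'   rate, M/s) and `n` (number of samples used).
#' @examples
#' tr <- kinetic_trace(seq(0, 100, 2), 1e-3 * seq(0, 100, 2))
#' initial_rate(tr, epsilon = 1000)  # 1e-6 M/s
#' @export
initial_rate <- function(trace, epsilon, pathlength_cm = 1,
                         fit_window_s = 60) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("epsilon must be positive", call. = FALSE)
  }
  keep <- trace$times <= trace$times[1] + fit_window_s
  if (sum(keep) < 3L) {
    stop("fewer than 3 samples inside the fit window", call. = FALSE)
  }
  fit <- stats::lm(a ~ t, data = data.frame(t = trace$times[keep],
                                            a = trace$absorbance[keep]))
  sl <- suppressWarnings(stats::coef(summary(fit))["t", ])
  rate <- unname(sl["Estimate"]) / (epsilon * pathlength_cm)
  attr(rate, "std_error") <- unname(sl["Std. Error"]) /
    (epsilon * pathlength_cm)
  attr(rate, "n") <- sum(keep)
  rate
}

#' Observed second-order rate constant
#'
#' By the law of mass action the observed constant of the whole process is
#' the initial rate divided by the product of the initial substrate and
#' dissolved-oxygen concentrations: `k = omega0 / (c0 * c_o2)`.  Its small
#' value relative to the propagation constants (1e4-1e5 per M per s) is
#' what identifies anion-to-oxygen electron transfer as the limiting
#' initiation step.
#'
#' @param omega0 Initial rate, M/s.
#' @param c0 Initial substrate concentration, M (> 0).
#' @param c_o2 Dissolved-oxygen concentration, M (> 0).
#' @return Rate constant in per M per s.
#' @examples
#' observed_rate_constant(8.7e-7, 2.6e-4, 2.51e-4)  # ~13.3
#' @export
observed_rate_constant <- function(omega0, c0, c_o2) {
  if (!is.numeric(c0) || any(c0 <= 0) || !is.numeric(c_o2) ||
      any(c_o2 <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  omega0 / (c0 * c_o2)
}

#' Pointwise antioxidant activity
#'
#' The classical index: relative suppression of the absorbance increase at
#' one antioxidant dose,
#' `AOA = (1 - delta_exp / delta_ctrl) * 100` percent.  Negative values
#' indicate a prooxidant effect (the dose accelerates product formation).
#'
#' @param delta_exp Blank-corrected absorbance increase with antioxidant,
#'   AU.
#' @param delta_ctrl Blank-corrected control absorbance increase, AU
#'   (> 0).
#' @return Activity in percent; vectorized over `delta_exp`.
#' @export
aoa_pointwise <- function(delta_exp, delta_ctrl) {
  if (!is.numeric(delta_ctrl) || any(delta_ctrl <= 0)) {
    stop("delta_ctrl must be positive", call. = FALSE)
  }
  (1 - delta_exp / delta_ctrl) * 100
}

#' A dose-response curve of the autoxidation assay
#'
#' Pairs antioxidant doses with blank-corrected absorbance increases.
#' Because the dose dependence is non-monotone (U-shaped), activity must be
#' assessed from a dose scan rather than a single dose.
#'
#' @param doses Antioxidant doses, strictly increasing.  Either molar
#'   concentrations (pure compounds) or added volumes in microlitres
#'   (extracts); state which in `dose_unit`.
#' @param responses Blank-corrected absorbance increases, AU.
#' @param dose_unit Unit label, e.g. `"M"` or `"uL"`.
#' @param pooled_sd Optional pooled replicate standard deviation of the
#'   responses (AU), used for the default U-shape noise margin.
#' @param n_replicates Number of replicates each response is a mean of.
#' @return Object of class `conc_response` with summary fields
#'   `minimum_dose` and `is_u_shaped` unset until
#'   [characterize_u_shape()] is applied.
#' @export
concentration_response <- function(doses, responses, dose_unit = "M",
                                   pooled_sd = NULL, n_replicates = 1L) {
  stopifnot(is.numeric(doses), is.numeric(responses))
  if (length(doses) != length(responses) || length(doses) < 1L) {
    stop("doses and responses must have equal length >= 1", call. = FALSE)
  }
  if (any(diff(doses) <= 0)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  structure(
    list(doses = doses, responses = responses, dose_unit = dose_unit,
         pooled_sd = pooled_sd, n_replicates = n_replicates,
         minimum_dose = NA_real_, is_u_shaped = NA),
    class = "conc_response"
  )
}

#' @export
print.conc_response <- function(x, ...) {
  cat(sprintf("Dose-response: %d doses (%s)\n", length(x$doses),
              x$dose_unit))
  print(data.frame(dose = x$doses, response_AU = x$responses))
  if (!is.na(x$is_u_shaped)) {
    cat(sprintf("  minimum at %g %s; U-shaped: %s\n", x$minimum_dose,
                x$dose_unit, x$is_u_shaped))
  }
  invisible(x)
}

#' @export
plot.conc_response <- function(x, log = "x", ...) {
  plot(x$doses, x$responses, type = "b", log = log,
       xlab = sprintf("dose (%s)", x$dose_unit),
       ylab = expression(Delta * D[347] ~ "(AU)"), ...)
  if (!is.na(x$is_u_shaped) && x$is_u_shaped) {
    abline(v = x$minimum_dose, lty = 2)
  }
  invisible(x)
}

#' Locate the activity optimum and test for a U shape
#'
#' Finds the dose of minimal response (maximal inhibition) and flags the
#' curve as U-shaped when that minimum is at an interior dose and both
#' neighbouring responses exceed it by more than a noise margin.  Monotone
#' curves are reported with `is_u_shaped = FALSE`.
#'
#' @param curve A [concentration_response()] with at least 3 doses.
#' @param noise_margin Margin in AU a neighbour must exceed the minimum by.
#'   Default: twice the standard deviation of the response values being
#'   compared — the pooled replicate standard deviation divided by the
#'   square root of the per-dose replicate count when the responses are
#'   replicate means — falling back to 0.01 AU when no replicate
#'   information is attached.
#' @return The curve with `minimum_dose` and `is_u_shaped` filled in, and
#'   attribute `noise_margin` recording the margin used.
#' @export
characterize_u_shape <- function(curve, noise_margin = NULL) {
  stopifnot(inherits(curve, "conc_response"))
  n <- length(curve$doses)
  if (n < 3L) stop("U-shape characterization needs >= 3 doses",
                   call. = FALSE)
  if (is.null(noise_margin)) {
    noise_margin <- if (!is.null(curve$pooled_sd)) {
      2 * curve$pooled_sd / sqrt(max(1L, curve$n_replicates))
    } else 0.01
  }
  i <- which.min(curve$responses)
  curve$minimum_dose <- curve$doses[i]
  curve$is_u_shaped <- i > 1L && i < n &&
    curve$responses[i - 1L] > curve$responses[i] + noise_margin &&
    curve$responses[i + 1L] > curve$responses[i] + noise_margin
  attr(curve, "noise_margin") <- noise_margin
  curve
}

#' Minimum-based (modified) antioxidant activity
#'
#' Because the dose-response is U-shaped, a single-dose index under- or
#' overstates activity depending on where the dose happens to sit.  The
#' modified index evaluates the suppression at the dose of maximal
#' inhibitory efficiency:
#' `AOA = (delta_ctrl - min(responses)) / delta_ctrl * 100` percent.
#' With a single-dose curve this reduces to the pointwise index.
#'
#' @param curve A [concentration_response()] (non-empty).
#' @param delta_ctrl Blank-corrected control absorbance increase, AU (> 0).
#' @return Object of class `aoa_result`: list with `aoa_percent`,
#'   `delta_ctrl`, `delta_min`, `minimum_dose`, `dose_unit`, `formula`.
#' @examples
#' curve <- concentration_response(c(2, 7) * 1e-6, c(0.148, 0.17))
#' aoa_modified(curve, delta_ctrl = 0.411)  # 64.0 %
#' @export
aoa_modified <- function(curve, delta_ctrl) {
  stopifnot(inherits(curve, "conc_response"))
  if (!is.numeric(delta_ctrl) || delta_ctrl <= 0) {
    stop("delta_ctrl must be positive", call. = FALSE)
  }
  i <- which.min(curve$responses)
  delta_min <- curve$responses[i]
  structure(
    list(aoa_percent = (delta_ctrl - delta_min) / delta_ctrl * 100,
         delta_ctrl = delta_ctrl, delta_min = delta_min,
         minimum_dose = curve$doses[i], dose_unit = curve$dose_unit,
         formula = if (length(curve$doses) == 1L) "eq_pointwise"
                   else "eq_minimum"),
    class = "aoa_result"
  )
}

#' @export
print.aoa_result <- function(x, ...) {
  cat(sprintf(
    "AOA = %.1f %% (control dD347 = %.3f, minimum dD347 = %.3f at %g %s)\n",
    x$aoa_percent, x$delta_ctrl, x$delta_min, x$minimum_dose, x$dose_unit))
  invisible(x)
}

#' Simulated dose-response of the inhibited assay
#'
#' Runs the antioxidant mechanism across a dose grid and collects the
#' absorbance increase over the analysis window into a
#' [concentration_response()].  Simulated systems have no sample
#' self-absorbance, so the responses are already blank-corrected.
#'
#' @param mech An `autox_mechanism` containing the antioxidant species
#'   (see [default_mechanism()] with `antioxidant_present = TRUE`).
#' @param doses Antioxidant concentrations, M, strictly increasing.
#' @param window_s Analysis window, seconds (default 180).
#' @param c0,o2,pathlength_cm Assay conditions.
#' @param duration_s,sample_interval_s Simulated trace layout.
#' @return A `conc_response` with molar doses.
#' @export
dose_response <- function(mech, doses, window_s = 180, c0 = 2.6e-4,
                          o2 = 2.51e-4, pathlength_cm = 1,
                          duration_s = 600, sample_interval_s = 2) {
  stopifnot(inherits(mech, "autox_mechanism"))
  times <- seq(0, duration_s, by = sample_interval_s)
  responses <- vapply(doses, function(d) {
    init <- default_initial_state(c0 = c0, o2 = o2, ao = d,
                                  pathlength_cm = pathlength_cm)
    course <- simulate_course(mech, init, times)
    delta_d(course_to_trace(course), window_s)
  }, numeric(1))
  concentration_response(doses, responses, dose_unit = "M")
}
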