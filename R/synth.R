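# Synthetic experiment generator: simulated spectrophotometer traces and
# DPPH endpoint records with the statistical structure the analysis
# assumes, so every downstream stage can be exercised and validated
# without measured data.

#' Measurement noise model
#'
#' Additive Gaussian noise, appropriate for spectrophotometric
#' shot/electronic noise at low absorbance, plus an optional linear
#' baseline drift.
#'
#' @param sd_absorbance Noise standard deviation, AU (default 0.005,
#'   consistent with the replicate spreads of the assay).
#' @param baseline_drift_per_s Linear baseline drift, AU per second
#'   (default 0).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sd_absorbance = 0.005, baseline_drift_per_s = 0,
                        seed = NULL) {
  stopifnot(sd_absorbance >= 0)
  structure(list(sd_absorbance = sd_absorbance,
                 baseline_drift_per_s = baseline_drift_per_s,
                 seed = seed),
            class = "noise_model")
}

#' Design of a synthetic kinetic experiment
#'
#' @param control_replicates Number of control (no antioxidant) traces.
#' @param ao_doses Antioxidant doses, M, non-negative and increasing.
#' @param dose_replicates Replicate traces per dose.
#' @param include_blanks Also emit paired no-substrate blank traces?
#' @param duration_s Trace duration, seconds (default 600: a 10-min run).
#' @param sample_interval_s Sampling interval, seconds (default 2,
#'   i.e. 0.5 Hz).
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(control_replicates = 3,
                              ao_doses = c(0.75, 1.5, 7.5, 15, 37.5) * 1e-6,
                              dose_replicates = 1,
                              include_blanks = TRUE,
                              duration_s = 600, sample_interval_s = 2) {
  stopifnot(duration_s > 0, sample_interval_s > 0,
            control_replicates >= 1, dose_replicates >= 1)
  if (length(ao_doses) && (any(ao_doses < 0) || any(diff(ao_doses) <= 0))) {
    stop("ao_doses must be non-negative and strictly increasing",
         call. = FALSE)
  }
  structure(list(control_replicates = control_replicates,
                 ao_doses = ao_doses, dose_replicates = dose_replicates,
                 include_blanks = include_blanks, duration_s = duration_s,
                 sample_interval_s = sample_interval_s),
            class = "experiment_design")
}

# run fn with a private RNG stream (restores the caller's stream)
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic kinetic dataset
#'
#' Simulates the mechanism at every dose of the design, adds measurement
#' noise and drift, and emits the corresponding traces: control
#' replicates, dose replicates, and (optionally) paired no-substrate
#' blanks, which carry no chromophore signal and are flat apart from
#' noise and drift.  Deterministic given `noise$seed`.
#'
#' @param design An [experiment_design()].
#' @param mech Mechanism to simulate; needs the antioxidant species when
#'   `design$ao_doses` are positive.  Default: the calibrated antioxidant
#'   mechanism.
#' @param noise A [noise_model()].
#' @param c0,o2,pathlength_cm Assay conditions.
#' @return List of [kinetic_trace()] objects.  Each trace carries
#'   attributes `dose` (M; `NA` for controls' blanks pairing, 0 for
#'   controls) and `replicate`.  The list carries attribute `truth`
#'   recording the generating mechanism and design.
#' @export
generate_kinetic_dataset <- function(design = experiment_design(),
                                     mech = default_mechanism(TRUE),
                                     noise = noise_model(),
                                     c0 = 2.6e-4, o2 = 2.51e-4,
                                     pathlength_cm = 1) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(mech, "autox_mechanism"),
            inherits(noise, "noise_model"))
  times <- seq(0, design$duration_s, by = design$sample_interval_s)
  doses <- c(0, design$ao_doses)
  reps <- c(design$control_replicates,
            rep(design$dose_replicates, length(design$ao_doses)))

  signals <- lapply(doses, function(d) {
    init <- default_initial_state(c0 = c0, o2 = o2, ao = d,
                                  pathlength_cm = pathlength_cm)
    simulate_course(mech, init, times)$absorbance_347
  })

  with_seed(noise$seed, function() {
    traces <- list()
    drift <- noise$baseline_drift_per_s * times
    for (i in seq_along(doses)) {
      base <- if (i == 1) "control" else sprintf("dose_%g", doses[i])
      for (r in seq_len(reps[i])) {
        a <- signals[[i]] + drift +
          stats::rnorm(length(times), 0, noise$sd_absorbance)
        tr <- kinetic_trace(times, a, 347,
                            label = sprintf("%s_r%d", base, r),
                            contains_substrate = TRUE)
        attr(tr, "dose") <- doses[i]
        attr(tr, "replicate") <- r
        traces <- c(traces, list(tr))
      }
      if (design$include_blanks) {
        a <- drift + stats::rnorm(length(times), 0, noise$sd_absorbance)
        bl <- kinetic_trace(times, a, 347,
                            label = sprintf("%s_blank", base),
                            contains_substrate = FALSE)
        attr(bl, "dose") <- doses[i]
        traces <- c(traces, list(bl))
      }
    }
    attr(traces, "truth") <- list(mechanism = mech, design = design,
                                  noise = noise, c0 = c0, o2 = o2)
    traces
  })
}

#' Reduce a synthetic (or measured) dataset to a dose-response curve
#'
#' Computes the windowed absorbance increase of every substrate-containing
#' trace, subtracts the paired blank's increase (scalar blank correction,
#' as in the tabulated assay; `blank_mode = "pointwise"` instead subtracts
#' the blank trace sample by sample before the increase is taken),
#' averages replicates per dose, and returns the control increase together
#' with the dose-response curve.  The pooled replicate standard deviation
#' is attached to the curve for the U-shape noise margin.
#'
#' @param dataset List of traces as from [generate_kinetic_dataset()]
#'   (traces must carry `dose` attributes; blanks are recognised by
#'   `contains_substrate = FALSE`).
#' @param window_s Analysis window, seconds.
#' @param blank_mode `"scalar"` or `"pointwise"`.
#' @return List with `delta_ctrl` (mean control increase, AU),
#'   `curve` (a [concentration_response()] over the positive doses) and
#'   `n_traces`.
#' @export
analyze_dataset <- function(dataset, window_s = 180,
                            blank_mode = c("scalar", "pointwise")) {
  blank_mode <- match.arg(blank_mode)
  doses <- vapply(dataset, function(tr) {
    d <- attr(tr, "dose")
    if (is.null(d)) NA_real_ else d
  }, numeric(1))
  if (anyNA(doses)) stop("every trace needs a 'dose' attribute",
                         call. = FALSE)
  is_blank <- !vapply(dataset, `[[`, TRUE, "contains_substrate")

  dd_one <- function(tr, blank) {
    if (is.null(blank) || blank_mode == "scalar") {
      d <- delta_d(tr, window_s)
      if (!is.null(blank)) d <- blank_correct(d, delta_d(blank, window_s))
      d
    } else {
      a <- tr$absorbance - stats::approx(blank$times, blank$absorbance,
                                         xout = tr$times)$y
      delta_d(kinetic_trace(tr$times, a, tr$wavelength_nm, tr$label),
              window_s)
    }
  }

  levels <- sort(unique(doses))
  per_dose <- lapply(levels, function(d) {
    sys <- dataset[doses == d & !is_blank]
    bl <- dataset[doses == d & is_blank]
    blank <- if (length(bl)) bl[[1]] else NULL
    vapply(sys, dd_one, numeric(1), blank = blank)
  })
  means <- vapply(per_dose, mean, numeric(1))
  # pooled replicate standard deviation across dose groups with >= 2 reps
  devs <- unlist(lapply(per_dose, function(v) if (length(v) > 1) v - mean(v)))
  dfree <- sum(vapply(per_dose, function(v) max(0L, length(v) - 1L),
                      integer(1)))
  pooled_sd <- if (dfree > 0) sqrt(sum(devs^2) / dfree) else NULL

  pos <- levels > 0
  curve <- if (any(pos)) {
    concentration_response(
      levels[pos], means[pos], dose_unit = "M", pooled_sd = pooled_sd,
      n_replicates = max(1L, length(per_dose[[which(pos)[1]]])))
  } else NULL
  list(delta_ctrl = if (any(!pos)) means[!pos] else NA_real_,
       curve = curve, n_traces = length(dataset))
}

#' Generate synthetic DPPH endpoint records
#'
#' Inverts the DPPH quantitation: for each true antioxidant concentration
#' the implied noiseless (blank, test) absorbance pair is computed, noise
#' is added, and the records are returned together with the generating
#' truth (attribute `truth`, mg/L).
#'
#' @param true_cao_mgl True antioxidant concentrations, mg/L rutin
#'   equivalents, non-negative.
#' @param noise A [noise_model()]; `sd_absorbance` applies to both
#'   absorbances.
#' @param v_extract_ml Extract volume per record, mL.
#' @param d_blank Noiseless blank absorbance, AU.
#' @param dpph0,v_system_ml,stoichiometric_coefficient,mgl_factor Assay
#'   constants, as in [dpph_record()].
#' @return List of [dpph_record()]s with attribute `truth`.
#' @export
generate_dpph_dataset <- function(true_cao_mgl, noise = noise_model(),
                                  v_extract_ml = 0.2, d_blank = 1.0,
                                  dpph0 = 8.1e-5, v_system_ml = 3.6,
                                  stoichiometric_coefficient = 3.1,
                                  mgl_factor = 6.1e5) {
  stopifnot(all(true_cao_mgl >= 0))
  zeta <- (true_cao_mgl / mgl_factor) * stoichiometric_coefficient *
    v_extract_ml / (dpph0 * v_system_ml)
  if (any(zeta > 1)) {
    stop(sprintf(
      "true concentration %.3g mg/L implies conversion degree %.2f > 1: use a smaller extract volume v_extract_ml",
      true_cao_mgl[which.max(zeta)], max(zeta)), call. = FALSE)
  }
  with_seed(noise$seed, function() {
    recs <- lapply(seq_along(zeta), function(i) {
      bl <- d_blank + stats::rnorm(1, 0, noise$sd_absorbance)
      ex <- d_blank * (1 - zeta[i]) + stats::rnorm(1, 0, noise$sd_absorbance)
      dpph_record(d_exp = max(0, ex), d_blank = bl,
                  v_extract_ml = v_extract_ml, dpph0 = dpph0,
                  v_system_ml = v_system_ml,
                  stoichiometric_coefficient = stoichiometric_coefficient,
                  mgl_factor = mgl_factor,
                  label = sprintf("synthetic_%d", i))
    })
    attr(recs, "truth") <- true_cao_mgl
    recs
  })
}
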