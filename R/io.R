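# File formats, run configuration and the pipeline entry point that the
# command-line wrapper (inst/cli/adrenox) drives.

#' Write / read a kinetic trace as CSV
#'
#' Traces are stored as two-column CSV files `time_s,absorbance`, one file
#' per reaction system.  By convention the paired no-substrate blank of
#' `<label>.csv` is stored as `<label>.blank.csv`; files following that
#' convention are read back with `contains_substrate = FALSE`.
#'
#' @param trace A [kinetic_trace()].
#' @param path File path.
#' @return `write_trace_csv`: the path, invisibly.  `read_trace_csv`: a
#'   [kinetic_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  utils::write.csv(data.frame(time_s = trace$times,
                              absorbance = trace$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param label Trace label; defaults to the file name.
#' @param wavelength_nm Analytical wavelength of the stored trace.
#' @export
read_trace_csv <- function(path, label = NULL, wavelength_nm = 347) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "absorbance") %in% names(df))) {
    stop("trace CSV needs columns time_s,absorbance: ", path,
         call. = FALSE)
  }
  if (is.null(label)) label <- sub("\\.csv$", "", basename(path))
  kinetic_trace(df$time_s, df$absorbance, wavelength_nm, label,
                contains_substrate = !grepl("\\.blank$", label))
}

#' Export a simulated course as CSV
#'
#' Column 1 `time_s`, column 2 `A347`, then one molar column per species.
#'
#' @param course An `autox_course`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_course_csv <- function(course, path) {
  stopifnot(inherits(course, "autox_course"))
  utils::write.csv(as.data.frame(course), path, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a mechanism
#'
#' Mechanisms are stored as YAML: the species table (id, role, 347-nm
#' extinction), the reaction list (reactants, products, rate constant,
#' label, step class, anion flag), and the medium block (pH, pKa's,
#' oxygen mode).
#'
#' @param mech An `autox_mechanism`.
#' @param path File path.
#' @return `write_mechanism`: the path, invisibly; `read_mechanism`: an
#'   `autox_mechanism`.
#' @export
write_mechanism <- function(mech, path) {
  stopifnot(inherits(mech, "autox_mechanism"))
  lst <- list(
    pH = mech$pH, pKa_substrate = mech$pKa_substrate,
    pKa_antioxidant = mech$pKa_antioxidant, oxygen_mode = mech$oxygen_mode,
    species = lapply(seq_len(nrow(mech$species)), function(i) {
      as.list(mech$species[i, ])
    }),
    reactions = lapply(mech$reactions, function(rx) {
      list(reactants = as.list(rx$reactants),
           products = as.list(rx$products), k = rx$k, label = rx$label,
           step = rx$step,
           anion = if (is.na(rx$anion)) NULL else rx$anion)
    })
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_mechanism
#' @export
read_mechanism <- function(path) {
  lst <- yaml::read_yaml(path)
  species <- do.call(rbind, lapply(lst$species, function(s) {
    autox_species(s$id, s$role, s$extinction_347)
  }))
  reactions <- lapply(lst$reactions, function(rx) {
    autox_reaction(unlist(rx$reactants), unlist(rx$products), rx$k,
                   rx$label %||% "", rx$step %||% "interconversion",
                   anion = rx$anion %||% NA_character_)
  })
  autox_mechanism(species, reactions, pH = lst$pH,
                  pKa_substrate = lst$pKa_substrate,
                  pKa_antioxidant = lst$pKa_antioxidant,
                  oxygen_mode = lst$oxygen_mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default run configuration
#'
#' The assay defaults: pH 10.65 carbonate buffer conditions, 2.6e-4 M
#' adrenaline, 2.51e-4 M dissolved oxygen, 1-cm cuvette, 180-s analysis
#' window, 60-s initial-rate window, the standard antioxidant dose series
#' (0.75-37.5 micromolar), and the DPPH constants (8.1e-5 M DPPH, 3.6 mL
#' system, stoichiometric coefficient 3.1, 6.1e5 mg/mol).
#'
#' @return Named list (class `adrenox_config`).
#' @export
default_config <- function() {
  structure(list(
    pH = 10.65, pKa_substrate = 9.9, pKa_antioxidant = 9.9,
    oxygen_mode = "closed",
    c0 = 2.6e-4, o2 = 2.51e-4, pathlength_cm = 1,
    window_s = 180, fit_window_s = 60, noise_margin = NULL,
    doses = c(0.75, 1.5, 7.5, 15, 37.5) * 1e-6,
    duration_s = 600, sample_interval_s = 2,
    constants = list(),
    noise_sd = 0.005, drift_per_s = 0,
    control_replicates = 3, dose_replicates = 1, include_blanks = TRUE,
    dpph = list(dpph0 = 8.1e-5, v_system_ml = 3.6,
                stoichiometric_coefficient = 3.1, mgl_factor = 6.1e5),
    mechanism_file = NULL,
    outdir = ".", log_level = "info"
  ), class = "adrenox_config")
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills every absent field with the assay
#' default, and validates the result.  Schema violations are collected
#' and reported field by field in a single error.  An empty (or absent
#' `""`) file yields the full default configuration.
#'
#' @param path Path to a YAML file, or `""` for pure defaults.
#' @return An `adrenox_config` list.
#' @export
load_config <- function(path = "") {
  user <- list()
  if (nzchar(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- utils::modifyList(unclass(default_config()), user)
  if (length(cfg$doses) > 1) cfg$doses <- as.numeric(cfg$doses)

  problems <- character()
  need_pos <- c("c0", "o2", "pathlength_cm", "window_s", "fit_window_s",
                "duration_s", "sample_interval_s", "noise_sd")
  for (f in need_pos) {
    v <- cfg[[f]]
    ok <- is.numeric(v) && length(v) == 1L && !is.na(v) &&
      (v > 0 || (f == "noise_sd" && v >= 0))
    if (!ok) problems <- c(problems, sprintf(
      "%s: must be a single positive number (got %s)", f,
      paste(format(v), collapse = ",")))
  }
  if (!is.numeric(cfg$pH) || cfg$pH < 7 || cfg$pH > 13) {
    problems <- c(problems, "pH: must lie in [7, 13]")
  }
  if (!cfg$oxygen_mode %in% c("closed", "clamped")) {
    problems <- c(problems, "oxygen_mode: must be 'closed' or 'clamped'")
  }
  if (length(cfg$doses) && (any(cfg$doses < 0) ||
                            any(diff(cfg$doses) <= 0))) {
    problems <- c(problems,
                  "doses: must be non-negative and strictly increasing")
  }
  for (f in names(default_config()$dpph)) {
    v <- cfg$dpph[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      problems <- c(problems, sprintf("dpph.%s: must be positive", f))
    }
  }
  if (!is.null(cfg$mechanism_file) && !file.exists(cfg$mechanism_file)) {
    problems <- c(problems,
                  sprintf("mechanism_file: not found (%s)",
                          cfg$mechanism_file))
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(cfg, class = "adrenox_config")
}

#' @rdname load_config
#' @param config Configuration to save.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

# mechanism implied by a configuration
config_mechanism <- function(config, antioxidant_present = FALSE) {
  if (!is.null(config$mechanism_file)) {
    read_mechanism(config$mechanism_file)
  } else {
    default_mechanism(antioxidant_present = antioxidant_present,
                      constants = config$constants, pH = config$pH,
                      pKa_substrate = config$pKa_substrate,
                      pKa_antioxidant = config$pKa_antioxidant,
                      oxygen_mode = config$oxygen_mode)
  }
}

log_msg <- function(config, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

write_report <- function(report, outdir, stem) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  json <- file.path(outdir, paste0(stem, ".json"))
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- json
  flat <- Filter(function(x) is.atomic(x) && length(x) >= 1, report)
  if (length(flat)) {
    csv <- file.path(outdir, paste0(stem, ".csv"))
    n <- max(vapply(flat, length, integer(1)))
    df <- as.data.frame(lapply(flat, function(x) {
      length(x) <- n
      x
    }))
    utils::write.csv(df, csv, row.names = FALSE)
    files <- c(files, csv)
  }
  files
}

#' Run a pipeline stage
#'
#' Top-level entry point behind the command-line wrapper.  Executes one
#' stage of the analysis and writes a machine-readable JSON report (plus
#' a flat CSV mirror of its scalar/vector fields) into the configured
#' output directory.
#'
#' Modes:
#' \describe{
#'   \item{`simulate`}{Simulate the control system (or one dose via
#'     `dose`) and write the full course CSV and its 347-nm trace.}
#'   \item{`analyze`}{Read `control`, optional `blank`, and `experiment`
#'     trace CSVs; report windowed increases, blank-corrected values,
#'     the control initial rate and the observed rate constant.}
#'   \item{`aoa`}{Compute the pointwise and minimum-based activity
#'     indices from literal `delta_ctrl`, `doses`, `responses` values.}
#'   \item{`dpph`}{Read a CSV `label,d_blank,d_exp,v_extract_ml` and
#'     report conversion degrees and antioxidant concentrations.}
#'   \item{`scan`}{Simulate the dose-response over `config$doses`,
#'     characterize the U shape and report the activity indices.}
#'   \item{`synth`}{Generate a synthetic dataset (traces + manifest)
#'     under the configured seed.}
#' }
#'
#' @param config An `adrenox_config` (see [load_config()]).
#' @param mode One of `"simulate"`, `"analyze"`, `"aoa"`, `"dpph"`,
#'   `"scan"`, `"synth"`.
#' @param ... Mode-specific arguments (see Details).
#' @param seed Integer seed for modes that draw random numbers.
#' @return List with `status` (0 on success), `report`, and `files`
#'   written.  Errors raised by a stage propagate as R conditions; the
#'   CLI wrapper maps them to a non-zero exit status.
#' @export
run_pipeline <- function(config = default_config(),
                         mode = c("simulate", "analyze", "aoa", "dpph",
                                  "scan", "synth"),
                         ..., seed = NULL) {
  mode <- match.arg(mode)
  args <- list(...)
  outdir <- config$outdir %||% "."
  times <- seq(0, config$duration_s, by = config$sample_interval_s)

  report <- switch(
    mode,
    simulate = {
      dose <- args$dose %||% 0
      mech <- config_mechanism(config, antioxidant_present = dose > 0)
      init <- default_initial_state(c0 = config$c0, o2 = config$o2,
                                    ao = dose,
                                    pathlength_cm = config$pathlength_cm)
      course <- simulate_course(mech, init, times)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_course_csv(course, file.path(outdir, "course.csv"))
      write_trace_csv(course_to_trace(course),
                      file.path(outdir, "trace.csv"))
      list(mode = mode, dose = dose,
           delta_d = delta_d(course_to_trace(course), config$window_s),
           files = c("course.csv", "trace.csv"))
    },
    analyze = {
      if (is.null(args$control)) stop("analyze needs a control trace",
                                      call. = FALSE)
      ctrl <- read_trace_csv(args$control)
      exps <- lapply(args$experiment %||% character(), read_trace_csv)
      lens <- vapply(c(list(ctrl), exps), function(tr) length(tr$times),
                     integer(1))
      if (length(unique(lens)) > 1) {
        stop("trace lengths differ across files: ",
             paste(lens, collapse = ", "), call. = FALSE)
      }
      d_blank <- 0
      if (!is.null(args$blank)) {
        d_blank <- delta_d(read_trace_csv(args$blank), config$window_s)
      } else if (isTRUE(args$require_blank)) {
        stop("blank correction requested but no blank trace given",
             call. = FALSE)
      }
      eps <- args$epsilon %||% default_rate_constants()$extinction_alu
      d_ctrl <- blank_correct(delta_d(ctrl, config$window_s), d_blank)
      omega0 <- initial_rate(ctrl, epsilon = eps,
                             pathlength_cm = config$pathlength_cm,
                             fit_window_s = config$fit_window_s)
      d_exp <- vapply(exps, function(tr) {
        blank_correct(delta_d(tr, config$window_s), d_blank)
      }, numeric(1))
      list(mode = mode, delta_ctrl = d_ctrl, delta_blank = d_blank,
           delta_exp = d_exp,
           aoa_pointwise = if (length(d_exp))
             aoa_pointwise(d_exp, d_ctrl) else numeric(),
           omega0 = as.numeric(omega0),
           omega0_se = attr(omega0, "std_error"),
           observed_k = observed_rate_constant(as.numeric(omega0),
                                               config$c0, config$o2))
    },
    aoa = {
      if (is.null(args$delta_ctrl) || is.null(args$responses)) {
        stop("aoa needs delta_ctrl and responses", call. = FALSE)
      }
      doses <- args$doses %||% seq_along(args$responses)
      curve <- concentration_response(doses, args$responses,
                                      dose_unit = args$dose_unit %||% "M")
      res <- aoa_modified(curve, args$delta_ctrl)
      list(mode = mode, aoa_percent = res$aoa_percent,
           delta_ctrl = res$delta_ctrl, delta_min = res$delta_min,
           minimum_dose = res$minimum_dose,
           aoa_pointwise = aoa_pointwise(args$responses, args$delta_ctrl))
    },
    dpph = {
      if (is.null(args$input)) stop("dpph needs an input CSV",
                                    call. = FALSE)
      df <- utils::read.csv(args$input)
      need <- c("label", "d_blank", "d_exp", "v_extract_ml")
      if (!all(need %in% names(df))) {
        stop("dpph CSV needs columns ", paste(need, collapse = ","),
             call. = FALSE)
      }
      k <- config$dpph
      res <- lapply(seq_len(nrow(df)), function(i) {
        antioxidant_concentration(dpph_record(
          df$d_exp[i], df$d_blank[i], df$v_extract_ml[i],
          dpph0 = k$dpph0, v_system_ml = k$v_system_ml,
          stoichiometric_coefficient = k$stoichiometric_coefficient,
          mgl_factor = k$mgl_factor, label = df$label[i]))
      })
      list(mode = mode, label = df$label,
           zeta = vapply(res, `[[`, numeric(1), "zeta"),
           cao_mol_l = vapply(res, `[[`, numeric(1), "cao_mol_l"),
           cao_mg_l = vapply(res, `[[`, numeric(1), "cao_mg_l"))
    },
    scan = {
      mech <- config_mechanism(config, antioxidant_present = TRUE)
      ctrl <- simulate_course(
        mech, default_initial_state(c0 = config$c0, o2 = config$o2,
                                    pathlength_cm = config$pathlength_cm),
        times)
      d_ctrl <- delta_d(course_to_trace(ctrl), config$window_s)
      curve <- dose_response(mech, config$doses,
                             window_s = config$window_s, c0 = config$c0,
                             o2 = config$o2,
                             pathlength_cm = config$pathlength_cm,
                             duration_s = config$duration_s,
                             sample_interval_s = config$sample_interval_s)
      curve <- characterize_u_shape(curve,
                                    noise_margin = config$noise_margin %||% 0)
      res <- aoa_modified(curve, d_ctrl)
      list(mode = mode, doses = curve$doses, responses = curve$responses,
           delta_ctrl = d_ctrl, aoa_percent = res$aoa_percent,
           minimum_dose = curve$minimum_dose,
           is_u_shaped = curve$is_u_shaped)
    },
    synth = {
      design <- experiment_design(
        control_replicates = config$control_replicates,
        ao_doses = config$doses,
        dose_replicates = config$dose_replicates,
        include_blanks = config$include_blanks,
        duration_s = config$duration_s,
        sample_interval_s = config$sample_interval_s)
      mech <- config_mechanism(config, antioxidant_present = TRUE)
      nm <- noise_model(config$noise_sd, config$drift_per_s, seed = seed)
      ds <- generate_kinetic_dataset(design, mech, nm, c0 = config$c0,
                                     o2 = config$o2,
                                     pathlength_cm = config$pathlength_cm)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      for (tr in ds) {
        write_trace_csv(tr, file.path(outdir, paste0(tr$label, ".csv")))
      }
      list(mode = mode, seed = seed, n_traces = length(ds),
           doses = design$ao_doses,
           labels = vapply(ds, `[[`, "", "label"))
    }
  )

  files <- write_report(report, outdir, paste0("report_", mode))
  log_msg(config, "info", "%s: report written to %s", mode, files[1])
  invisible(list(status = 0L, report = report, files = files))
}
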