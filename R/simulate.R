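# Mass-action integration of a mechanism and derived course statistics.

#' Initial state of a reaction system
#'
#' @param concentrations Named numeric vector of molar concentrations
#'   (species absent from the vector start at zero).  All values must be
#'   non-negative.
#' @param pathlength_cm Optical path length of the cuvette in cm.
#' @return An object of class `autox_state`.
#' @export
initial_state <- function(concentrations, pathlength_cm = 1) {
  stopifnot(is.numeric(concentrations), !is.null(names(concentrations)))
  if (any(is.na(concentrations)) || any(concentrations < 0)) {
    bad <- names(concentrations)[is.na(concentrations) | concentrations < 0]
    stop("negative or missing initial concentration for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(pathlength_cm > 0)
  structure(list(concentrations = concentrations,
                 pathlength_cm = pathlength_cm),
            class = "autox_state")
}

#' Default initial state for the standard assay
#'
#' Control conditions of the alkaline autoxidation assay: 2.6e-4 M
#' adrenaline and 2.51e-4 M dissolved oxygen (the air-equilibrium value at
#' 25 C) in a 1-cm cuvette, with an optional antioxidant dose.
#'
#' @param c0 Initial substrate (adrenaline) concentration, M.
#' @param o2 Initial dissolved-oxygen concentration, M.
#' @param ao Antioxidant concentration, M (ignored unless the mechanism
#'   contains the antioxidant species).
#' @param pathlength_cm Cuvette path length, cm.
#' @return An `autox_state`.
#' @export
default_initial_state <- function(c0 = 2.6e-4, o2 = 2.51e-4, ao = 0,
                                  pathlength_cm = 1) {
  conc <- c(EPI = c0, O2 = o2)
  if (ao > 0) conc <- c(conc, AO = ao)
  initial_state(conc, pathlength_cm)
}

# Precompute the vectorized mass-action rate-law data for a mechanism:
# stoichiometry matrix, reactant indices, and effective rate constants
# with the anionic pre-equilibrium factor folded in.
compile_network <- function(mech) {
  sp <- mech$species$id
  nr <- length(mech$reactions)
  S <- matrix(0, length(sp), nr, dimnames = list(sp, NULL))
  i1 <- integer(nr)
  i2 <- rep(NA_integer_, nr)
  keff <- numeric(nr)
  for (j in seq_len(nr)) {
    rx <- mech$reactions[[j]]
    for (s in rx$reactants) S[s, j] <- S[s, j] - 1
    for (s in rx$products)  S[s, j] <- S[s, j] + 1
    i1[j] <- match(rx$reactants[1], sp)
    if (length(rx$reactants) == 2L) i2[j] <- match(rx$reactants[2], sp)
    f <- 1
    if (!is.na(rx$anion)) {
      role <- mech$species$role[match(rx$anion, sp)]
      pKa <- if (role %in% .antioxidant_roles) mech$pKa_antioxidant
             else mech$pKa_substrate
      f <- anionic_fraction(mech$pH, pKa)
    }
    keff[j] <- rx$k * f
  }
  bi <- !is.na(i2)
  list(species = sp, S = S, i1 = i1, i2 = i2, bi = bi, keff = keff,
       o2_idx = match("O2", sp))
}

# reaction rates (M/s) at one concentration vector
network_rates <- function(net, y) {
  v <- net$keff * y[net$i1]
  v[net$bi] <- v[net$bi] * y[net$i2[net$bi]]
  v
}

#' Integrate a mechanism over a time grid
#'
#' Solves the mass-action rate equations with a stiff-capable integrator
#' (`deSolve::lsoda`).  Reactions flagged as proceeding through a phenolate
#' anion have their rate multiplied by the anionic fraction of the relevant
#' total concentration (fast acid-base pre-equilibrium).  In
#' `oxygen_mode = "clamped"` the O2 concentration is held at its initial
#' value; in `"closed"` mode it depletes as in a sealed cuvette.
#'
#' @param mech An `autox_mechanism`.
#' @param init An `autox_state` (default: standard assay conditions).
#' @param times Strictly increasing numeric vector of output times in
#'   seconds, starting at 0.
#' @param rtol,atol Relative and absolute solver tolerances.  The defaults
#'   (1e-8, 1e-12 M) resolve radical concentrations of order 1e-7 M.
#'
#' @return An object of class `autox_course`: list with `times`,
#'   `concentrations` (time x species matrix, M), `absorbance_347`
#'   (`pathlength * sum(extinction * concentration)` over all species) and
#'   the generating mechanism/state.
#' @examples
#' mech <- default_mechanism()
#' course <- simulate_course(mech, times = seq(0, 180, 2))
#' plot(course)
#' @export
simulate_course <- function(mech, init = default_initial_state(),
                            times = seq(0, 600, 2),
                            rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(mech, "autox_mechanism"), inherits(init, "autox_state"))
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) stop("times must start at 0", call. = FALSE)
  extra <- setdiff(names(init$concentrations), mech$species$id)
  if (length(extra)) {
    stop("initial state names species absent from the mechanism: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }

  net <- compile_network(mech)
  y0 <- stats::setNames(numeric(length(net$species)), net$species)
  y0[names(init$concentrations)] <- init$concentrations
  clamp_o2 <- identical(mech$oxygen_mode, "clamped") && !is.na(net$o2_idx)

  rhs <- function(t, y, parms) {
    dy <- as.vector(net$S %*% network_rates(net, y))
    if (clamp_o2) dy[net$o2_idx] <- 0
    list(dy)
  }
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    diag <- utils::capture.output(deSolve::diagnostics(out))
    stop("ODE solver failed to converge (istate = ", istate, "):\n",
         paste(diag, collapse = "\n"), call. = FALSE)
  }
  conc <- out[, net$species, drop = FALSE]
  eps <- mech$species$extinction_347[match(net$species, mech$species$id)]
  a347 <- init$pathlength_cm * as.vector(conc %*% eps)
  structure(
    list(times = out[, "time"], concentrations = conc,
         absorbance_347 = a347, mechanism = mech, init = init,
         rtol = rtol, atol = atol),
    class = "autox_course"
  )
}

#' @export
as.data.frame.autox_course <- function(x, ...) {
  data.frame(time_s = x$times, A347 = x$absorbance_347,
             x$concentrations, check.names = FALSE)
}

#' @export
print.autox_course <- function(x, ...) {
  cat(sprintf("Simulated course: %d time points over %.0f s, %d species\n",
              length(x$times), max(x$times), ncol(x$concentrations)))
  cat(sprintf("  A347: %.4f -> %.4f AU\n",
              x$absorbance_347[1], x$absorbance_347[length(x$times)]))
  invisible(x)
}

#' @export
plot.autox_course <- function(x, ...) {
  plot(x$times, x$absorbance_347, type = "l", xlab = "time (s)",
       ylab = "A347 (AU)", ...)
  invisible(x)
}

#' Kinetic chain length over a time window
#'
#' Ratio of the time-averaged propagation flux to the time-averaged
#' initiation flux, the mean number of propagation events each initiation
#' event gives rise to.  A long chain (tens of links) is the signature of
#' chain autoxidation: sub-stoichiometric amounts of a scavenger can then
#' suppress a large fraction of the product formation.
#'
#' @param course An `autox_course`.
#' @param mech The generating mechanism (defaults to the one stored in the
#'   course).
#' @param window Length-2 numeric, time window in seconds.
#' @return Non-negative number; `Inf` (with a warning) when the initiation
#'   flux integral is zero.
#' @export
kinetic_chain_length <- function(course, mech = course$mechanism,
                                 window = c(0, 180)) {
  stopifnot(inherits(course, "autox_course"), length(window) == 2L)
  t <- course$times
  if (window[1] < t[1] || window[2] > t[length(t)]) {
    stop("window must lie within the simulated span", call. = FALSE)
  }
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 2L) stop("window contains fewer than 2 samples",
                           call. = FALSE)
  net <- compile_network(mech)
  steps <- vapply(mech$reactions, `[[`, "", "step")
  rates <- t(apply(course$concentrations[keep, , drop = FALSE], 1,
                   function(y) network_rates(net, y)))
  tt <- t[keep]
  trapz <- function(v) sum(diff(tt) * (v[-1] + v[-length(v)]) / 2)
  init_int <- trapz(rowSums(rates[, steps == "initiation", drop = FALSE]))
  prop_int <- trapz(rowSums(rates[, steps == "propagation", drop = FALSE]))
  if (init_int <= 0) {
    warning("zero initiation flux over the window: chain length is infinite")
    return(Inf)
  }
  prop_int / init_int
}
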