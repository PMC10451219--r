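# Reaction-network representation of alkaline epinephrine autoxidation.
#
# The chain is carried by superoxide: the phenolate anion of the catechol
# reduces O2 (initiation), superoxide oxidizes the catechol to its
# semiquinone (propagation a), and the semiquinone reduces O2 back to
# superoxide (propagation b).  The quinone cyclizes to leukoadrenochrome,
# which is chain-oxidized in the same way to adrenochrome, and adrenochrome
# isomerizes to adrenolutin, the 347-nm chromophore.  A phenolic antioxidant
# enters through the structurally analogous reactions plus superoxide
# scavenging, chain transfer and radical-radical termination.

#' Valid species roles
#'
#' Roles classify a species within the reaction network: which skeleton it
#' belongs to (substrate-derived, antioxidant-derived, or oxygen-derived),
#' and whether it contributes to the 347-nm absorbance.
#' @keywords internal
#' @noRd
.species_roles <- c(
  "substrate", "substrate_anion", "semiquinone", "quinone",
  "cyclic_intermediate", "chromophore_adrenochrome",
  "chromophore_adrenolutin", "oxygen", "superoxide", "peroxide",
  "antioxidant", "antioxidant_anion", "antioxidant_radical",
  "antioxidant_quinone", "inert_product"
)

# skeleton membership by role: substrate-derived material and
# antioxidant-derived material must each be conserved by every reaction
.substrate_roles <- c(
  "substrate", "substrate_anion", "semiquinone", "quinone",
  "cyclic_intermediate", "chromophore_adrenochrome",
  "chromophore_adrenolutin"
)
.antioxidant_roles <- c(
  "antioxidant", "antioxidant_anion", "antioxidant_radical",
  "antioxidant_quinone"
)

#' Define a chemical species
#'
#' @param id Short symbolic name, unique within a mechanism.
#' @param role One of the recognised roles (see Details).
#' @param extinction_347 Molar absorptivity at 347 nm (per M per cm),
#'   non-negative.  Zero for species that do not absorb at the analytical
#'   wavelength.
#'
#' @details Recognised roles: `r paste(.species_roles, collapse = ", ")`.
#'   The role determines skeleton membership for the conservation audit:
#'   substrate-derived roles (catechol through adrenolutin) carry one unit
#'   of substrate skeleton, antioxidant-derived roles one unit of
#'   antioxidant skeleton.
#'
#' @return A one-row data frame with columns `id`, `role`, `extinction_347`.
#' @export
autox_species <- function(id, role, extinction_347 = 0) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  role <- match.arg(role, .species_roles)
  if (!is.numeric(extinction_347) || length(extinction_347) != 1L ||
      is.na(extinction_347) || extinction_347 < 0) {
    stop("extinction_347 must be a single non-negative number", call. = FALSE)
  }
  data.frame(id = id, role = role, extinction_347 = extinction_347,
             stringsAsFactors = FALSE)
}

#' Define an elementary reaction
#'
#' @param reactants Character vector of species ids (1 or 2, duplicates
#'   allowed for e.g. radical disproportionation).
#' @param products Character vector of species ids.
#' @param k Rate constant: per second for unimolecular steps, per molar per
#'   second for bimolecular steps.  Non-negative.
#' @param label Free-text label tying the step to the underlying chemistry.
#' @param step Kinetic class of the step, used by
#'   [kinetic_chain_length()]: `"initiation"`, `"propagation"`,
#'   `"termination"`, `"interconversion"`, `"scavenging"` or `"transfer"`.
#' @param anion Id of a reactant that reacts through its phenolate anion,
#'   or `NA`.  For such reactions the rate is multiplied by the anionic
#'   fraction of that species' total concentration (fast acid-base
#'   pre-equilibrium; see [anionic_fraction()]).
#'
#' @return A list of class `autox_reaction`.
#' @export
autox_reaction <- function(reactants, products, k, label = "",
                           step = c("interconversion", "initiation",
                                    "propagation", "termination",
                                    "scavenging", "transfer"),
                           anion = NA_character_) {
  step <- match.arg(step)
  stopifnot(is.character(reactants), is.character(products))
  if (length(reactants) < 1L || length(reactants) > 2L) {
    stop("a reaction must have 1 or 2 reactant molecules", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0) {
    stop("rate constant must be a single non-negative number", call. = FALSE)
  }
  if (!is.na(anion) && !(anion %in% reactants)) {
    stop("anion species must be one of the reactants", call. = FALSE)
  }
  structure(
    list(reactants = reactants, products = products, k = k,
         label = label, step = step, anion = anion),
    class = "autox_reaction"
  )
}

#' Assemble a reaction mechanism
#'
#' Bundles species, reactions and medium conditions, and audits the network
#' for internal consistency: every reaction may only reference declared
#' species, and substrate-derived and antioxidant-derived material must be
#' conserved by each reaction individually.
#'
#' @param species Data frame of species rows from [autox_species()]
#'   (row-bound).
#' @param reactions List of [autox_reaction()] objects.
#' @param pH Medium pH, in \[7, 13\].
#' @param pKa_substrate,pKa_antioxidant Phenolic pKa used for the anionic
#'   pre-equilibrium partition of the respective totals.
#' @param oxygen_mode `"closed"` (dissolved O2 depletes from its initial
#'   value, as in a cuvette) or `"clamped"` (O2 held constant).
#'
#' @return An object of class `autox_mechanism`.
#' @seealso [default_mechanism()], [simulate_course()]
#' @export
autox_mechanism <- function(species, reactions, pH = 10.65,
                            pKa_substrate = 9.9, pKa_antioxidant = 9.9,
                            oxygen_mode = c("closed", "clamped")) {
  oxygen_mode <- match.arg(oxygen_mode)
  stopifnot(is.data.frame(species),
            all(c("id", "role", "extinction_347") %in% names(species)))
  if (anyDuplicated(species$id)) {
    stop("species ids must be unique", call. = FALSE)
  }
  if (!is.numeric(pH) || pH < 7 || pH > 13) {
    stop("pH must lie in [7, 13]", call. = FALSE)
  }
  mech <- structure(
    list(species = species, reactions = reactions, pH = pH,
         pKa_substrate = pKa_substrate, pKa_antioxidant = pKa_antioxidant,
         oxygen_mode = oxygen_mode),
    class = "autox_mechanism"
  )
  audit_mechanism(mech)
  mech
}

#' Audit skeleton conservation of a mechanism
#'
#' Checks reaction by reaction that the number of substrate-skeleton
#' molecules (catechol and all of its downstream oxidation states) among the
#' reactants equals that among the products, and likewise for the
#' antioxidant skeleton.  Stops with an informative error on the first
#' violation; returns `TRUE` invisibly otherwise.
#'
#' @param mech An `autox_mechanism`.
#' @return `TRUE`, invisibly.
#' @export
audit_mechanism <- function(mech) {
  sk <- skeleton_counts(mech$species)
  for (i in seq_along(mech$reactions)) {
    rx <- mech$reactions[[i]]
    unknown <- setdiff(c(rx$reactants, rx$products), mech$species$id)
    if (length(unknown)) {
      stop(sprintf("reaction %d ('%s') references undeclared species: %s",
                   i, rx$label, paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    for (col in c("substrate", "antioxidant")) {
      lhs <- sum(sk[rx$reactants, col])
      rhs <- sum(sk[rx$products, col])
      if (lhs != rhs) {
        stop(sprintf(
          "reaction %d ('%s') does not conserve the %s skeleton (%d -> %d)",
          i, rx$label, col, lhs, rhs), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# per-species skeleton membership matrix (rows named by id)
skeleton_counts <- function(species) {
  m <- cbind(
    substrate = as.integer(species$role %in% .substrate_roles),
    antioxidant = as.integer(species$role %in% .antioxidant_roles)
  )
  rownames(m) <- species$id
  m
}

#' Anionic fraction of a phenol at a given pH
#'
#' Fraction of a phenolic hydroxyl present as the phenolate anion, from the
#' Henderson-Hasselbalch relation `1 / (1 + 10^(pKa - pH))`.  The anion is
#' the species that reduces molecular oxygen in the rate-limiting initiation
#' step, so the observed autoxidation rate grows with pH through this
#' fraction.
#'
#' @param pH Medium pH.
#' @param pKa Phenolic pKa.
#' @return Fraction in \[0, 1\], monotonically increasing in pH.
#' @examples
#' anionic_fraction(9.9, 9.9)    # half-ionization: 0.5
#' anionic_fraction(10.65, 9.9)  # assay conditions: ~0.849
#' @export
anionic_fraction <- function(pH, pKa) {
  1 / (1 + 10^(pKa - pH))
}

#' Default rate constants of the calibrated mechanism
#'
#' Named list of the rate constants used by [default_mechanism()].  The
#' propagation constants of the substrate (`k_prop_sub_sup`,
#' `k_prop_sq_o2`) are the literature order-of-magnitude estimates 1e4 and
#' 1e5 per M per s.  `k_init` is not measurable directly; its default is
#' the value calibrated so that the simulated control trace reproduces the
#' observed initial rate of 8.7e-7 M/s (see [calibrate_initiation()]).
#' `extinction_alu` is calibrated so the control three-minute absorbance
#' increase falls at 0.38 AU, inside the observed control range
#' 0.356-0.411.  The antioxidant constants are effective values chosen once
#' to reproduce the qualitative behaviour of phenolic inhibitors in this
#' system (strong superoxide scavenging relative to the substrate, weak
#' chain propagation by the phenoxyl radical, and a prooxidant regime at
#' high dose); see the package vignette for the reasoning.
#'
#' @return Named list of rate constants and optical coefficients.
#' @export
default_rate_constants <- function() {
  list(
    # substrate chain
    k_init          = 0.62991, # anion + O2, calibrated to omega0
    k_prop_sub_sup  = 1e4,     # catechol + superoxide
    k_prop_sq_o2    = 1e5,     # semiquinone + O2
    k_cyclization   = 0.5,     # quinone -> leukoadrenochrome, 1/s
    k_prop_lac_sup  = 1e6,     # leukoadrenochrome + superoxide
    k_prop_asq_o2   = 1e6,     # adrenochrome semiquinone + O2
    k_isomerization = 0.1,     # adrenochrome -> adrenolutin, 1/s
    k_sup_disprop   = 1e5,     # superoxide disproportionation
    k_sq_disprop    = 1e6,     # semiquinone disproportionation
    # antioxidant analogue chain
    k_init_ao       = 10,      # antioxidant anion + O2
    k_scavenge      = 2e5,     # antioxidant + superoxide
    k_prop_aor_o2   = 1e3,     # antioxidant radical + O2 (weak)
    k_cross_term    = 1e7,     # antioxidant radical + substrate semiquinone
    k_self_term     = 1e4,     # antioxidant radical self-termination
    k_transfer      = 1e4,     # antioxidant radical + substrate (chain transfer)
    # optics at 347 nm
    extinction_alu  = 3685,    # adrenolutin, per M per cm (calibrated)
    extinction_ach_frac = 0.1  # adrenochrome, as fraction of adrenolutin's
  )
}

#' Default mechanism of epinephrine autoxidation
#'
#' Builds the calibrated reaction network: anion-mediated initiation,
#' superoxide-carried propagation through semiquinone and quinone,
#' cyclization to leukoadrenochrome, second-stage chain oxidation to
#' adrenochrome, isomerization to adrenolutin (the 347-nm chromophore), and
#' superoxide/semiquinone disproportionation.  With
#' `antioxidant_present = TRUE` the structurally analogous antioxidant
#' steps are added: anion initiation, superoxide scavenging, weak
#' re-reduction of O2 by the antioxidant radical, chain transfer back to
#' the substrate, and cross/self radical-radical termination.
#'
#' @param antioxidant_present Include the phenolic-antioxidant reactions?
#' @param constants Named list as from [default_rate_constants()]; entries
#'   override the defaults.
#' @param pH,pKa_substrate,pKa_antioxidant,oxygen_mode Passed to
#'   [autox_mechanism()].
#'
#' @return An `autox_mechanism`.
#' @examples
#' mech <- default_mechanism()
#' print(mech)
#' @export
default_mechanism <- function(antioxidant_present = FALSE,
                              constants = list(), pH = 10.65,
                              pKa_substrate = 9.9, pKa_antioxidant = 9.9,
                              oxygen_mode = "closed") {
  p <- utils::modifyList(default_rate_constants(), constants)
  eps_alu <- p$extinction_alu
  eps_ach <- p$extinction_ach_frac * eps_alu

  species <- rbind(
    autox_species("EPI",  "substrate"),
    autox_species("SQ",   "semiquinone"),
    autox_species("Q",    "quinone"),
    autox_species("LAC",  "cyclic_intermediate"),
    autox_species("ASQ",  "semiquinone"),
    autox_species("ACH",  "chromophore_adrenochrome", eps_ach),
    autox_species("ALU",  "chromophore_adrenolutin", eps_alu),
    autox_species("O2",   "oxygen"),
    autox_species("SUP",  "superoxide"),
    autox_species("H2O2", "peroxide")
  )

  reactions <- list(
    autox_reaction(c("EPI", "O2"), c("SQ", "SUP"), p$k_init,
                   "initiation: catechol anion + O2", "initiation",
                   anion = "EPI"),
    autox_reaction(c("EPI", "SUP"), c("SQ", "H2O2"), p$k_prop_sub_sup,
                   "propagation a: catechol + superoxide", "propagation"),
    autox_reaction(c("SQ", "O2"), c("Q", "SUP"), p$k_prop_sq_o2,
                   "propagation b: semiquinone + O2", "propagation"),
    autox_reaction("Q", "LAC", p$k_cyclization,
                   "cyclization: quinone -> leukoadrenochrome",
                   "interconversion"),
    autox_reaction(c("LAC", "SUP"), c("ASQ", "H2O2"), p$k_prop_lac_sup,
                   "propagation a': leukoadrenochrome + superoxide",
                   "propagation"),
    autox_reaction(c("ASQ", "O2"), c("ACH", "SUP"), p$k_prop_asq_o2,
                   "propagation b': adrenochrome semiquinone + O2",
                   "propagation"),
    autox_reaction("ACH", "ALU", p$k_isomerization,
                   "isomerization: adrenochrome -> adrenolutin",
                   "interconversion"),
    autox_reaction(c("SUP", "SUP"), c("O2", "H2O2"), p$k_sup_disprop,
                   "termination: superoxide disproportionation",
                   "termination"),
    autox_reaction(c("SQ", "SQ"), c("Q", "EPI"), p$k_sq_disprop,
                   "termination: semiquinone disproportionation",
                   "termination")
  )

  if (antioxidant_present) {
    species <- rbind(
      species,
      autox_species("AO",  "antioxidant"),
      autox_species("AOR", "antioxidant_radical"),
      autox_species("AOQ", "antioxidant_quinone")
    )
    reactions <- c(reactions, list(
      autox_reaction(c("AO", "O2"), c("AOR", "SUP"), p$k_init_ao,
                     "initiation: antioxidant anion + O2", "initiation",
                     anion = "AO"),
      autox_reaction(c("AO", "SUP"), c("AOR", "H2O2"), p$k_scavenge,
                     "scavenging: antioxidant + superoxide", "scavenging"),
      autox_reaction(c("AOR", "O2"), c("AOQ", "SUP"), p$k_prop_aor_o2,
                     "propagation: antioxidant radical + O2 (weak)",
                     "propagation"),
      autox_reaction(c("AOR", "EPI"), c("AO", "SQ"), p$k_transfer,
                     "chain transfer: antioxidant radical + catechol",
                     "transfer"),
      autox_reaction(c("AOR", "SQ"), c("AOQ", "EPI"), p$k_cross_term,
                     "termination: cross, antioxidant radical + semiquinone",
                     "termination"),
      autox_reaction(c("AOR", "AOR"), c("AOQ", "AO"), p$k_self_term,
                     "termination: antioxidant radical self", "termination")
    ))
  }

  autox_mechanism(species, reactions, pH = pH,
                  pKa_substrate = pKa_substrate,
                  pKa_antioxidant = pKa_antioxidant,
                  oxygen_mode = oxygen_mode)
}

#' @export
print.autox_mechanism <- function(x, ...) {
  cat(sprintf(
    "Epinephrine autoxidation mechanism: %d species, %d reactions\n",
    nrow(x$species), length(x$reactions)))
  cat(sprintf("  pH %.2f (pKa substrate %.2f, antioxidant %.2f), oxygen %s\n",
              x$pH, x$pKa_substrate, x$pKa_antioxidant, x$oxygen_mode))
  for (rx in x$reactions) {
    cat(sprintf("  %-34s k = %-8.3g  [%s]\n",
                paste(paste(rx$reactants, collapse = " + "), "->",
                      paste(rx$products, collapse = " + ")),
                rx$k, rx$step))
  }
  invisible(x)
}

#' Set a named rate constant inside a mechanism
#'
#' Convenience for calibration: replaces the rate constant of every
#' reaction whose label or step matches.
#' @keywords internal
#' @noRd
set_reaction_rate <- function(mech, match_label, k) {
  hit <- FALSE
  for (i in seq_along(mech$reactions)) {
    if (grepl(match_label, mech$reactions[[i]]$label, fixed = TRUE)) {
      mech$reactions[[i]]$k <- k
      hit <- TRUE
    }
  }
  if (!hit) stop("no reaction labelled '", match_label, "'", call. = FALSE)
  mech
}
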