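# Shared fixtures and independent oracles.

# Reduced chain network: initiation plus one propagation pair, oxygen
# clamped.  Small enough that early-time product growth has a closed-form
# solution, which serves as an independent oracle for the ODE integrator.
reduced_mechanism <- function(k1 = 0.005, k2 = 1e3, k3 = 1e4,
                              pH = 12.9, pKa = 9.9) {
  species <- rbind(
    autox_species("EPI", "substrate"),
    autox_species("SQ", "semiquinone"),
    autox_species("Q", "quinone"),
    autox_species("O2", "oxygen"),
    autox_species("SUP", "superoxide"),
    autox_species("H2O2", "peroxide")
  )
  reactions <- list(
    autox_reaction(c("EPI", "O2"), c("SQ", "SUP"), k1,
                   "initiation: catechol anion", "initiation",
                   anion = "EPI"),
    autox_reaction(c("EPI", "SUP"), c("SQ", "H2O2"), k2,
                   "propagation a", "propagation"),
    autox_reaction(c("SQ", "O2"), c("Q", "SUP"), k3,
                   "propagation b", "propagation")
  )
  autox_mechanism(species, reactions, pH = pH, pKa_substrate = pKa,
                  oxygen_mode = "clamped")
}

# Closed-form early-time solution of the reduced clamped-oxygen network,
# valid while substrate depletion is negligible ([EPI] ~ E0).  With
#   a = k1 * f_anion * E0 * c   (initiation rate, constant)
#   b = k2 * E0                 (superoxide consumption coefficient)
#   g = k3 * c                  (semiquinone turnover coefficient)
# the radical balance is linear:
#   u' = a - b u + g s,  s' = a + b u - g s   (u = [SUP], s = [SQ])
# so u + s = 2 a t, and with c1 = b + g
#   u(t) = p t + q (1 - exp(-c1 t)),  p = 2 a g / c1,  q = (a - p) / c1
#   s(t) = 2 a t - u(t)
#   Q(t) = g * integral(s) =
#          g * (a t^2 - p t^2 / 2 - q t + (q / c1) (1 - exp(-c1 t)))
reduced_oracle <- function(times, k1 = 0.005, k2 = 1e3, k3 = 1e4,
                           pH = 12.9, pKa = 9.9, E0 = 2.6e-4,
                           c_o2 = 2.51e-4) {
  f <- anionic_fraction(pH, pKa)
  a <- k1 * f * E0 * c_o2
  b <- k2 * E0
  g <- k3 * c_o2
  c1 <- b + g
  p <- 2 * a * g / c1
  q <- (a - p) / c1
  u <- p * times + q * (1 - exp(-c1 * times))
  s <- 2 * a * times - u
  Q <- g * (a * times^2 - p * times^2 / 2 - q * times +
              (q / c1) * (1 - exp(-c1 * times)))
  data.frame(time = times, SUP = u, SQ = s, Q = Q)
}

# simulated control trace under standard assay conditions (memoised:
# several test files reuse it)
control_course <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_course(default_mechanism(),
                                times = seq(0, 600, 2))
    }
    cache
  }
})

# per-time-point totals of a skeleton across a simulated course
skeleton_totals <- function(course, ids) {
  present <- intersect(ids, colnames(course$concentrations))
  rowSums(course$concentrations[, present, drop = FALSE])
}

substrate_ids <- c("EPI", "SQ", "Q", "LAC", "ASQ", "ACH", "ALU")
antioxidant_ids <- c("AO", "AOR", "AOQ")
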