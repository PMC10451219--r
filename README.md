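# adrenox

Kinetic modelling of alkaline epinephrine (adrenaline) autoxidation and
the spectrophotometric antioxidant assay built on it, plus DPPH-based
antioxidant quantitation. For researchers who use the adrenaline system
to measure superoxide-scavenging activity — or who want to understand,
before trusting a single-dose activity number, why that system's
dose-response is U-shaped.

## The model

Adrenaline autoxidation in carbonate buffer (pH 10.65) is a
superoxide-carried chain:

    initiation     HO-Ar-O⁻ + O₂  →  HO-Ar-O• + O₂•⁻        (rate-limiting)
    propagation a  HO-Ar-OH + O₂•⁻ →  •O-Ar-O⁻ + H₂O₂        k ≈ 10⁴ M⁻¹s⁻¹
    propagation b  •O-Ar-O⁻ + O₂  →  O=Ar=O + O₂•⁻           k ≈ 10⁵ M⁻¹s⁻¹

followed by cyclization to leukoadrenochrome, chain oxidation to
adrenochrome, and isomerization to adrenolutin, the 347-nm chromophore
that the spectrophotometer tracks. The anionic fraction entering the
initiation rate comes from the Henderson–Hasselbalch partition
1/(1 + 10^(pKa − pH)), which is what makes the observed rate grow with
pH. The package integrates the mass-action network with a stiff solver
(`deSolve`) and computes the assay's statistics:

* ΔD₃₄₇ — blank-corrected absorbance increase over the first 3 min;
* ω₀ — initial rate from the trace slope, and the observed second-order
  constant k = ω₀ / (C₀ · C_O₂);
* AOA = (1 − ΔD_exp/ΔD_ctrl) · 100 % (pointwise) and the minimum-based
  index AOA = (ΔD_ctrl − ΔD_exp,min)/ΔD_ctrl · 100 %, which evaluates
  activity at the dose of maximal inhibition of a U-shaped dose scan;
* DPPH quantitation: ζ = 1 − D_exp/D_bl and
  C_AO = [DPPH]₀·V_syst·ζ/(3.1·V_es) in rutin equivalents.

A phenolic antioxidant enters the mechanism through structurally
analogous steps (anion initiation, superoxide scavenging, weak radical
propagation, chain transfer, radical–radical termination); with the
calibrated defaults the simulated dose-response reproduces the
characteristic U shape — inhibition up to an interior optimum, then a
prooxidant reversal. A synthetic-data module generates noisy traces and
DPPH records with known ground truth for end-to-end validation.

## Worked example

```r
library(adrenox)

mech   <- default_mechanism()                       # calibrated control network
course <- simulate_course(mech, times = seq(0, 600, 2))
trace  <- course_to_trace(course)

delta_d(trace)
#> [1] 0.38
rate <- initial_rate(trace, epsilon = default_rate_constants()$extinction_alu)
as.numeric(rate)
#> [1] 8.7e-07
observed_rate_constant(as.numeric(rate), c0 = 2.6e-4, c_o2 = 2.51e-4)
#> [1] 13.33
kinetic_chain_length(course, window = c(0, 180))
#> [1] 180.1

ao    <- default_mechanism(antioxidant_present = TRUE)
curve <- dose_response(ao, 10^seq(-7, -4, length.out = 9))
characterize_u_shape(curve, noise_margin = 0)
#> Dose-response: 9 doses (M)
#> ...
#>   minimum at 1.77828e-05 M; U-shaped: TRUE
aoa_modified(curve, delta_ctrl = delta_d(trace))
#> AOA = 28.0 % (control dD347 = 0.380, minimum dD347 = 0.274 at 1.77828e-05 M)
```

Reading the numbers: the control trace gains 0.38 AU in 3 min; its
initial slope corresponds to 8.7e-7 M/s of product formation, an
observed constant of 13.3 M⁻¹s⁻¹ on total concentrations — far below the
propagation constants, confirming initiation as the limiting step. The
chain length (~180 propagation events per initiation) explains why
micromolar antioxidant doses matter at 260 µM substrate. The dose scan
shows the U shape: maximal inhibition (28 %) near 18 µM, prooxidant
reversal above it.

A thin command-line wrapper ships in the package:

```sh
$(Rscript -e 'cat(system.file("cli", "adrenox", package = "adrenox"))') \
    scan --outdir out/
```

with subcommands `simulate`, `analyze`, `aoa`, `dpph`, `scan`, `synth`.

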