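Package: adrenox
Title: Kinetics of Epinephrine Autoxidation and Superoxide-Scavenging
    Antioxidant Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Mass-action simulation of the superoxide-driven chain
    autoxidation of epinephrine (adrenaline) in alkaline medium, including
    inhibition and prooxidation by phenolic antioxidants.  Provides the
    kinetic-trace statistics used with this assay (blank-corrected
    three-minute absorbance increase at 347 nm, initial rate, observed
    second-order rate constant, pointwise and minimum-based antioxidant
    activity indices, U-shaped dose-response characterization), DPPH-based
    quantitation of total antioxidant content in rutin equivalents, and a
    synthetic spectrophotometer-trace generator so that every analysis
    stage can be exercised without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
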