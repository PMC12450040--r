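Package: deswax
Title: Hansen Solubility Screening and Dispersion Kinetics for Deep
    Eutectic Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening (hydrophobic natural) deep eutectic
    solvents against hydrophobic solutes such as beeswax. Computes
    Hoftyzer-Van Krevelen group-contribution Hansen solubility
    parameters for pure components, volume-fraction mixing rules and
    Teas fractions for binary (or n-ary) eutectic mixtures, Hansen
    distance (Ra) and relative energy difference (RED) compatibility
    scores with calibration of an unknown solute reference from
    observed RED values, and a saturation-limited Hill-type dispersion
    kinetics model with nonlinear least-squares fitting, a full
    regression statistics panel (R2, adjusted R2, SE, F, p, AIC, BIC,
    AICc), turbidity-mass linear calibration, and a seeded generator
    of paired turbidimetric/gravimetric dispersion time series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    deSolve,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
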