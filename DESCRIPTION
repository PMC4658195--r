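Package: gevikin
Title: Kinetic Modeling and Voltage-Clamp Fluorimetry Analysis for
    Genetically Encoded Voltage Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses voltage-clamp fluorimetry experiments on
    voltage-sensor-domain based fluorescent voltage indicators such as ArcLight.
    Provides a linear-chain Markov model of voltage-sensor gating in which the
    first transition carries gating charge and the last carries the fluorescence
    change, deterministic (eigendecomposition) and stochastic (Gillespie)
    solvers, generators for macroscopic gating-current plus fluorescence sweep
    families and for single-molecule TIRF recordings with EMCCD camera noise and
    fluorophore blinking, and the standard analysis operators: sloped-baseline
    subtraction, gating-charge integration, Boltzmann Q-V normalization,
    double-exponential kinetics with weighted time constants, fluorescence-lag
    extraction by abscissa crossing of exponential fits, blinking-noise
    autocorrelation with white-noise confidence bands, staged kinetic-scheme
    fitting, and three- versus four-state model discrimination under gating
    acceleration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
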