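Package: camiks
Title: Calmodulin-Variant IKs Biophysics and Ventricular Action-Potential
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@camiks.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studies of arrhythmia-associated calmodulin
    (CaM) variants acting on the slow delayed-rectifier potassium current
    (IKs, Kv7.1/KCNE1).  Covers whole-cell voltage-clamp analysis
    (current densities, normalised conductance, Boltzmann activation fits),
    one- and two-site isothermal titration calorimetry isotherm models and
    fits with full thermodynamic decomposition, NMR chemical-shift
    perturbation, thermal melt (Tm) fitting, limited-proteolysis
    densitometry, flow-cytometry surface-density arithmetic, and molar
    extinction coefficients from sequence composition.  Includes an
    O'Hara-Rudy CiPA human ventricular myocyte model with a Hill-type
    CaM-dependent IKs block whose block constant is calibrated against
    measured fractional current reductions to predict action-potential
    duration (APD50) changes, plus synthetic-data generators mirroring each
    assay so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
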