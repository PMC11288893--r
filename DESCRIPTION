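Package: condmat
Title: Phase-Separation Thermodynamics and Spectroscopic Analysis of Protein Condensate Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and quantifies the liquid-to-solid maturation of protein
    condensates such as FUS droplets. Implements a ternary Flory-Huggins
    free-energy model with monomer-aggregate conversion kinetics in coexisting
    phases (binodal and tie-line solving, lever rule, maturation trajectories),
    quantification of condensed versus dilute protein fractions from DOSY
    gradient decays, kinetic analysis of time-resolved CP/INEPT solid-state NMR
    spectra (region integration, 48-h normalization, linear rate fitting),
    Gaussian chemical-shift secondary-structure classification with 2D peak
    back-prediction, and Kramers-Kronig phase retrieval plus concentric-ring
    core-shell analysis for hyperspectral coherent Raman (BCARS) cubes. Seeded
    synthetic-data generators emulate every input class for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    signal,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
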