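Package: glycoslide
Title: Facilitated Diffusion and Intramolecular Site Transfer of DNA
    Glycosylases Under Molecular Crowding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and analysis of facilitated diffusion of
    DNA repair glycosylases on two-site DNA substrates. Provides a
    sliding-and-hopping lattice walker with an exact first-passage oracle, a
    population-level reaction sampler that emulates gel-based intramolecular
    site-transfer experiments, estimators for the overall, associative and
    dissociative site-transfer probabilities (zero-time extrapolation and
    molecular-clock trap partitioning), nonlinear fitting of stopped-flow
    association and dissociation traces, Michaelis-Menten steady-state
    parameters, anisotropy binding isotherms and ion-selective-electrode
    calibrations, and crowding-physics calculations (PEG radius of gyration,
    depletion layers, Stokes-Einstein deviation, kinetic partitioning of
    dissociative transfer).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
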