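Package: isoring
Title: Isodesmic Protein Self-Assembly with Preferential Ring Closure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Equilibrium modelling of noncooperative (isodesmic) protein
    polymerization coupled with size-dependent ring closure, as observed
    for single-strand-annealing proteins such as human RAD52. Provides
    the equilibrium species solver, global nonlinear fitting of the
    assembly model to oligomer titration data with bootstrap
    uncertainties, multi-Gaussian deconvolution of single-molecule
    mass-photometry histograms with AIC component selection, seeded
    synthetic-data generators for event lists, binding curves and
    annealing time courses, and cooperative ssDNA-binding (Hill) and
    annealing-kinetics calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
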