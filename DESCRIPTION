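Package: cavityfluct
Title: Solvent Density Fluctuations in Spherical Cavities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying length-scale-dependent solvent density
    fluctuations inside spherical observation volumes (cavities) in liquids.
    Provides an isothermal-isobaric Metropolis Monte Carlo engine for the
    coarse-grained mW water model (Stillinger-Weber two- plus three-body
    potential) with a mobile passive cavity probe, harmonic occupancy
    umbrella sampling, Widom test-particle insertion, and ideal-gas and
    hard-sphere reference solvents; reconstruction of the cavity occupancy
    distribution p_n by the weighted histogram analysis method and by a
    radial-distribution-function knitting estimator that joins
    occupancy-resolved cavity-solvent RDFs through continuity of the cavity
    correlation function; and an analytic layer comprising an interpolated
    Gaussian fluctuation theory and its augmentation with a bubble-nucleation
    branch (pressure-volume work plus surface tension on a Tolman-shifted
    interface), including nucleation-occupancy estimators and structural
    radius-of-gyration diagnostics of cavity emptying.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
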