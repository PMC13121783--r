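Package: spindleflux
Title: Stochastic Simulation of Kinetochore-Microtubule Error Correction
    with Microtubule Poleward Flux
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based Monte Carlo model of the metaphase spindle in one
    dimension: discrete tubulin lattices with plus-end polymerization and
    kinesin-13 driven minus-end depolymerization (poleward flux), kinesin-5
    sliding motors in antiparallel overlaps, NuMA crosslinkers, a quasi-static
    spring network positioning microtubules and the sister-kinetochore pair,
    catch-slip force-dependent kinetochore-microtubule detachment with
    Aurora-B tension-dependent destabilization, and distance-dependent
    reattachment.  Includes attachment-state classification (bi-oriented,
    merotelic, syntelic, monotelic), summary statistics (bi-orientation
    probability, first-passage times, flux rate, force statistics,
    oscillation periods, kinetochore-position amplitude), scenario presets
    for error-correction experiments, and parameter-sweep drivers.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
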