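Package: synquant
Title: Quantal Analysis of Evoked Synaptic Currents by
    Multiple-Probability Fluctuation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantal analysis of evoked excitatory postsynaptic
    currents (EPSCs) recorded in paired whole-cell configurations. Provides
    a generative binomial release-site simulator, stimulus-locked EPSC
    detection with kinetic and charge measurements, multiple-probability
    fluctuation analysis (MPFA) by weighted variance-mean parabola fitting
    with drift-robust pairwise variance, electron-microscopic active-zone
    vesicle classification and geometry estimators, and cross-species
    derived metrics (release sites per active zone, membrane area per
    release site, docking-site occupancy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
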