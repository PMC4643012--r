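Package: PatternEvents
Title: Variability-Shaped Spatiotemporal Patterns in Excitable Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulators and analysis tools for studying how fixed
    cell-to-cell variability shapes self-organized spatiotemporal
    patterns in excitable and Turing media. Provides five lattice
    models (a three-state excitable cellular automaton, the
    Schnakenberg Turing system, a FitzHugh-Nagumo lattice with static
    or developmental-path variability, a hybrid cellular-automaton/ODE
    model of Dictyostelium cAMP signaling, and the reduced
    three-variable Martiel-Goldbeter cAMP relay model with a
    developmental path), a pattern-event extraction layer that converts
    spatiotemporal movies into target-wave origins and
    chirality-resolved spiral tips via phase singularities, and
    ensemble statistics relating cell-property maps to event occupancy
    maps (Gaussian-filtered Spearman correlation curves, Voronoi-edge
    proximity tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    EBImage,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
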