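Package: netprox
Title: Network Proximity, Separation and Module Significance Screening on
    Interactomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how node sets (disease genes, drug targets) are
    positioned on a protein-protein interaction network. Computes all-pairs
    distance matrices under several graph metrics (shortest path, random walk
    with restart, degree-biased random walk, communicability), caches them to
    disk, and scores disease-module localization (largest-connected-component
    significance), drug-disease proximity and disease-disease separation
    against degree-aware null models, reporting Z-scores and empirical
    p-values. Includes an all-pairs screening engine that is deterministic
    under parallel execution, a synthetic benchmark generator with planted
    modules, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    optparse,
    parallel,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
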