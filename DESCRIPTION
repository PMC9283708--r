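Package: tumornet
Title: Brownian-Dynamics Tumor Growth and Contact-Network Phase Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of two-dimensional tumor growth by
    interacting cells and network-theoretic analysis of the resulting cell
    configurations.  Cells are unit-diameter discs performing overdamped
    Brownian motion with a short-range screened chemical attraction
    (modified Bessel-function pair force), stochastic birth and death, and
    hard-core overlap constraints.  Contact networks (edge when cell
    centers are within one diameter) are summarized by degree
    distribution, average and nearest-neighbor degree, transitivity,
    clustering and component structure; spatial observables include the
    pair distribution function and the radius of gyration.  Sweep
    utilities vary the attraction strength, differentiate the network
    measures against its inverse, and locate the solid-liquid-gas phase
    transitions of the growing tumor from the derivative peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
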