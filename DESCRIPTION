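Package: wingscape
Title: Theoretical Morphospace and Flight-Performance Landscapes for Insect Wing Outlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies closed two-dimensional wing outlines by elliptical
    Fourier analysis, builds an empirical principal-component morphospace and a
    regular grid of back-projected theoretical wing shapes, scores each viable
    shape for three antagonistic flight-performance proxies (aspect ratio,
    non-dimensional radius of the second moment of area, and median von Mises
    stress from a thin-plate finite-element bending model), and ranks shapes by
    a Pareto rank-ratio optimality score. Includes phylogenetic comparative
    tools (Brownian-motion ancestral state reconstruction, phylomorphospace
    projection, multivariate Blomberg K with a permutation test, and
    phylogenetic generalized least squares), a synthetic-data generator for
    wing-like outlines, pure-birth trees, Brownian traits and covariates, and a
    driver that runs the full pipeline from a configuration list.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    ggplot2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
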