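Package: fragesp
Title: Electrostatic and Shape Similarity of Anchored Molecular Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes electrostatic-potential (ESP) and volumetric shape
    similarity between molecules and molecular fragments from point-charge
    Coulomb fields, using either an analytic three-Gaussian expansion of 1/r
    or seeded Monte Carlo shell integration, with Carbo and Tanimoto metrics
    and a combined ESP-shape score. Fragments are produced by cutting
    ring-adjacent single bonds, aligned in a common frame through a rigid
    hexazine-methylene anchor, and compared pairwise to build a
    similarity-ordered balanced binary tree whose root-to-leaf paths yield
    compact fragment bitstrings. A small actor-critic generator swaps
    fragment codes in lead molecules to steer generation toward molecular
    weight, clogP and polar-surface-area target ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    igraph,
    minpack.lm,
    yaml,
    ChemmineR,
    ChemmineOB,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
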