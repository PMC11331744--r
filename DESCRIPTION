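Package: molfrag
Title: Automatic Molecular Fragmentation by Genetic-Algorithm Score Optimisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic fragmentation of molecular systems for many-body
    expansion (MBE) calculations. A molecule read from XYZ or PDB coordinates
    is represented as an attributed graph with perceived bonds, hybridisation,
    conjugated systems and hyperconjugated donor/acceptor pairs. Candidate
    fragmentations (binary cut vectors over allowed single bonds) are scored
    by a six-penalty function balancing chemical-environment preservation
    (force-field energy gap, conjugation, hyperconjugation) against
    fragment-size control (Gaussian-overlap volumes, volume range, fragment
    count), and the score is minimised by a genetic algorithm inside a
    recursive driver. Broken bonds are capped with hydrogens placed along the
    severed bond axis, fragment energies are assembled with the many-body
    expansion at the two- or three-body level, and the penalty weights can be
    re-tuned by Gaussian-process Bayesian optimisation on the probability
    simplex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    igraph,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
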