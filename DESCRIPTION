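Package: enerprof
Title: Alignment-Free Protein Comparison with Knowledge-Based Energy Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a distance-dependent knowledge-based statistical
    potential from heavy-atom Delaunay contacts in protein structures and
    summarises every protein as a 210-dimensional energy profile over
    unordered amino-acid pairs, computed either from coordinates (the
    structural profile of energy, SPE) or from sequence composition alone
    through a fitted 20x20 energy predictor matrix (the compositional
    profile of energy, CPE). Manhattan distances between profiles drive
    alignment-free comparison tools: nearest-neighbour classification with
    leave-one-out cross-validation, clustering evaluated by the adjusted
    Rand index, neighbour-joining and UPGMA trees with bootstrap supports,
    and an energy-based separation measure between two protein sets.
    Includes a deterministic synthetic-data generator so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    ape,
    mclust,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
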