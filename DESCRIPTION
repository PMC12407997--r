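Package: stsketch
Title: Spatially Aware Sketching and Benchmarking for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sketching (representative sub-sampling) of large spatial
    transcriptomics datasets and for benchmarking sketching designs. Implements
    uniform sampling, exact and randomized-projection leverage-score sampling,
    minimax (Hausdorff-coverage) and maximin (farthest-first) geometric designs,
    and a spatially aware leverage-score variant that smooths a randomized-SVD
    basis with a k-nearest-neighbour spatial weights matrix before scoring.
    Includes a zero-inflated negative-binomial simulator of gridded (Visium-like)
    and scattered (Xenium-like) tissues with striped, radial, and mosaic domain
    layouts, plus an evaluation framework: robust (partial) Hausdorff distances
    in expression and coordinate space, adjusted Rand index of sketch-derived
    clusters, principal-component projection drift, k-nearest-neighbour
    cell-type composition distortion, and a rank-sum overall spatial score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
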