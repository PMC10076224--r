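Package: storder
Title: Joint Trajectory Inference from Expression Connectivity and Spatial Cell Densities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cell-state differentiation trajectories by fusing a
    cluster-level expression connectivity matrix (PAGA-style, observed
    inter-state k-NN edges over their random expectation) with a spatial
    correlation matrix obtained by fitting a pairwise Gaussian-process model
    to per-spot cell-state density fields. Candidate trajectory trees are
    reconstructed as maximum spanning trees of the fused weights, screened
    against topology constraints (single branching point, fixed root and end
    states), and summarised over an (alpha, beta) weight grid. Also provides
    the empty-droplet "soup probability" statistic for flagging genes
    dominated by ambient RNA, and seeded synthetic-data generators (hex-lattice
    density landscapes, Gaussian-process pair draws, ambient-contaminated
    droplet matrices) so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
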