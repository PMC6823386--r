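Package: symcirc
Title: Symmetry-Group Analysis of Small Weighted Neural Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects exact and approximate (pseudo)symmetries of small
    weighted neural circuits such as the C. elegans locomotion
    connectome. Permutation symmetries are scored by an L1 commutator
    norm between the permutation and the weighted adjacency matrix,
    normalized by total link weight to give a dimensionless uncertainty
    constant. The symmetry group is factorized into normal subgroups
    acting on disjoint neuron sectors, each sector is decomposed into
    blocks of imprimitivity, and the blocks are matched to circulant and
    block-circulant matrices interpreted as high-pass, low-pass and
    subsampling signal-processing filters. Includes a degree-preserving
    null model for statistical significance, an idealization step that
    repairs a circuit to make approximate symmetries exact, a linear
    feedforward/recurrent rate model with eigenmode analysis, community
    detection and centrality baselines, and a synthetic-circuit
    generator with planted symmetry structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
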