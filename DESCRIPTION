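Package: gmnet
Title: Simulation and Analysis of Gene-Matched Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Construction and analysis of gene-matched networks (GMNs), in
    which neurons carry randomly assigned gene attributes and connectivity is
    determined by shared gene expression. Provides circular (single-layer)
    network construction with shared-gene edge multiplicities, small-world
    characterization against edge-matched random and ring-lattice reference
    networks, multi-layer feed-forward signal propagation with
    activation-percentage (top-k) thresholding, transmission polarity and
    combination ratios, the active-neuron and active-gene array codings,
    cross-layer consistency (L1-distance regression slope) reliability
    statistics, structural perturbation experiments (neuron removal,
    connection replacement and removal), and synthetic-photograph image-patch
    experiments including gene-array image search and per-neuron optimum
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
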