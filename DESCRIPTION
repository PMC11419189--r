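Package: dendrann
Title: Dendritic Artificial Neural Networks with Structured Sparse Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains two-hidden-layer image classifiers whose first
    ("dendritic") hidden layer samples restricted parts of the input image and
    connects to the second ("somatic") layer through a structured, tree-like
    boolean mask, mimicking the wiring of biological dendrites. Provides random,
    local-receptive-field and global-receptive-field input sampling schemes,
    gradient-masked Adam training that preserves the sparse wiring exactly,
    parameter-efficiency scores, interpretability analyses of hidden units
    (activation hit matrices, entropy, selectivity index, weight statistics),
    and embedding-quality metrics (silhouette, neighborhood hit,
    trustworthiness) for low-dimensional projections of hidden activations.
    Includes an IDX (MNIST-family) reader/writer and a synthetic image
    generator with spatially localized class information for desk-scale
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    Rtsne,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
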