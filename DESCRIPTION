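Package: neurostates
Title: Transcriptional States and Paracrine Networks from Single-Neuron qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for spatially-tracked single-neuron
    high-throughput qPCR and single-cell-scale RNA-seq of autonomic
    ganglia, modeled on studies of the cardiac right atrial ganglionic
    plexus. Implements failed-reaction quality control, median-reference
    -dCt/-ddCt normalization, a transcriptional-state model fitted by
    hierarchical clustering with Pavlidis template matching assignment
    and a silhouette permutation null, Kolmogorov-Smirnov differential
    screening between projection groups, combinatorial
    neuropeptide-receptor paracrine network construction, PCA-tail
    variable-gene selection, binary-template tissue enrichment, spatial
    gradient screens, and a synthetic-data generator with ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
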