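Package: netpea
Title: Network-Based Pathway Enrichment Analysis with Random Walks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pathway enrichment analysis on protein-protein interaction
    networks. Similarity between an input gene set and annotated pathways is
    measured by random walk with restart network propagation; statistical
    significance is assessed with permutation z-scores against randomized
    gene sets (NetPEA) or against jointly randomized gene sets and
    degree-preserving rewired networks (NetPEA'). Includes a hypergeometric
    over-representation baseline, utilities for comparing method rankings,
    a planted-module synthetic scenario generator, and a command-line
    interface over edge-list, GMT and gene-list files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
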