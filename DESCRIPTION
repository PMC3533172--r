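Package: stressnet
Title: Stress Time-Course Scoring and Mutual-Information Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reverse engineering of gene regulatory relationships from
    multi-condition abiotic stress time-course transcriptomes. Scores genes
    across stress series by summed absolute log2 fold changes (an "abiotic
    stress matrix"), ordinates condition groups by between-group analysis,
    infers gene-gene networks from mutual information (MRNET, CLR, ARACNE,
    C3NET, relevance networks) and from correlation and first-order partial
    correlation, and characterises the results (hub genes, ego subnetworks,
    gene-set overlap, hypergeometric enrichment, recovery metrics). Includes
    a synthetic-data generator that emulates a multi-stress, multi-time-point,
    two-tissue microarray design with an embedded ground-truth regulatory
    network, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
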