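Package: logicgrn
Title: Gene Regulatory Network Reconstruction with Probabilistic Continuous Logic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simultaneous reconstruction of gene regulatory network structure
    and of the logic functions among regulatory genes from continuous gene
    expression data scaled to [0, 1]. Candidate regulator subsets and k-input
    logic functions (defined over the 2^k activatory/inhibitory Venn
    partitions, under probabilistic-continuous or fuzzy semantics) are scored
    with a beta-distribution likelihood; models are selected by BIC and
    filtered by a Bayes factor against a non-informative null. Includes a
    seeded simulator of signed logical networks with beta-noise expression
    samples and evaluation metrics at the undirected, directed, and
    directed-logical (per-partition) levels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
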