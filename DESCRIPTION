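Package: drsn
Title: Construction and Analysis of Drug-Metabolic Subpathway Networks
Version: 0.1.0
Authors@R:
    person("DRSN", "Maintainers", email = "drsn@example.org", role = c("aut", "cre"))
Description: Builds a bipartite drug-metabolic subpathway network from drug
    perturbation expression profiles and metabolic pathway graphs. Subpathways
    are mined as maximal node sets with bounded pairwise graph distance
    (the k-clique method), drugs are linked to subpathways by hypergeometric
    enrichment of their differentially expressed genes, and the resulting
    network is characterised against degree-preserving randomised nulls.
    Downstream analyses quantify shared indications and side effects among
    co-linked drug pairs, score drug class to disease class associations
    through shared subpathways (fold enrichment ratios and association
    scores), and profile the tissue specificity of therapeutic versus
    non-therapeutic subpathways via tissue-homogeneity coefficients. A
    synthetic-data generator with planted structure makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
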