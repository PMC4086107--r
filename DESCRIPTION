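Package: seednet
Title: Seed-Based Protein-Protein Interaction Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable backend for seed-based protein-protein interaction
    (PPI) network analysis. Starting from gene lists or expression matrices,
    it runs differential expression with p-value and log fold-change seed
    selection, maps seeds onto a user-supplied interactome, constructs zero-,
    first- or higher-order subnetworks with trimming and manual exclusion,
    computes hub statistics (degree, betweenness centrality) and shortest
    paths, detects expression-weighted Walktrap modules with Wilcoxon
    rank-sum module significance, performs hypergeometric gene-set
    enrichment on node selections, and exports results as tab-delimited
    tables and GraphML. Includes synthetic fixture generators (scale-free
    interactomes, planted-community graphs, two-group expression matrices,
    random GMT collections) so the full workflow runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
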