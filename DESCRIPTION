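Package: assaynet
Title: Bioassay-Compound Networks and Network-Proximity Drug-Target
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds bioassay-compound bipartite networks from
    high-throughput screening activity tables, projects them onto assays by
    Jaccard similarity of active-compound sets, and characterizes the
    resulting network (degree distribution, power-law fit, clustering
    profile).  Maps bioassay target proteins into a protein-protein
    interaction network and tests, against randomized controls, whether they
    cluster around essential genes, approved drug targets and disease genes.
    Prioritizes bioassay targets as candidate drug targets via an
    inverse-square characteristic distance to essential genes and drug
    targets, with binned ranking and degree filtering.  Includes a synthetic
    data generator (preferential-attachment interactome, marker sets with
    planted proximity enrichment, clustered activity tables) so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
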