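Package: AlteredNet
Title: Altered-Gene Subnetwork Extraction and Network Module Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts disease-specific subnetworks from a curated gene
    interaction network and per-case genomic alteration calls. Recurrently
    altered genes are connected through the global network, statistically
    enriched linker genes are identified with a hypergeometric test and
    Benjamini-Hochberg correction, and the resulting subnetwork is
    partitioned into modules by iterative edge-betweenness removal with
    modularity-optimal stopping. Significance is assessed with a global
    random-gene-set null model for connectivity and a local
    degree-preserving rewiring null model for modularity. Includes a
    synthetic-data generator (random interaction networks, planted modules,
    alteration matrices) and Cytoscape-compatible output writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
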