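Package: pathexnet
Title: Pathway-Derived Protein Networks in an Expression-Specific Context
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Translates KEGG pathway charts (KGML files) into undirected
    protein networks keyed on UniProt accessions. Pathway relations are
    unified into a two-table relational store (proteins and pair-wise
    relations), from which "local" networks (the canonical pathway only)
    and "global" networks (one-hop expansion into the whole pathway
    corpus) are built. Gene-expression evidence (barcode-style
    fraction-of-samples-expressed scores, FPKM or EST counts) is overlaid
    to call each protein ON, OFF or NA in a cellular context, and
    networks are filtered to the expression-specific subnetwork.
    Physical-interaction pair lists decorate pathway edges, and per-node
    topology metrics (degree, betweenness, clustering coefficient,
    eigenvector centrality) identify hubs. Includes a synthetic-fixture
    generator with machine-readable ground truth so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
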