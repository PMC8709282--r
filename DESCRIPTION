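Package: ddsn
Title: Drug Repurposing with Drug-Drug Similarity Networks and
    Resolution-Tuned Modularity Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted drug-drug similarity networks (DDSN) from typed
    drug-gene interaction data, clusters them with a resolution-parameterized
    Louvain-style modularity optimizer, labels clusters with their dominant
    level-1 ATC (Anatomical Therapeutic Chemical) code, tunes the modularity
    resolution by maximizing repositionings confirmed between two dated ATC
    tables, and emits ranked drug repurposing hints. Reads DrugBank
    full-database XML exports as well as a plain TSV interchange format, and
    ships a seeded synthetic-fixture generator with planted community and
    repositioning structure so the whole pipeline is testable without any
    licensed download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2,
    jsonlite,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    withr
Config/testthat/edition: 3
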