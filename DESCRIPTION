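Package: hemaTFnet
Title: Discovery and Prioritization of Lineage-Restricted Transcription
    Factors in Hematopoiesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in-silico workflow for nominating lineage-restricted
    transcription factors (TFs) across hematopoietic cell groups from
    bulk RNA-seq count matrices. The pipeline filters and normalizes
    counts, tests differential expression of each lineage against the
    stem-cell group, scores lineage specificity, builds a signed
    weighted co-expression network with topological-overlap module
    detection, integrates co-expression edges with ChIP-derived and
    curated TF-target tables into a regulatory network, projects the
    network onto TFs with degree centrality and promoter-accessibility
    annotation, and emits a ranked candidate-TF table. A seeded
    synthetic-data generator with planted modules, group-restricted TFs
    and accessibility truth makes every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    fgsea,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
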