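Package: epigrn
Title: Context-Specific Gene Regulatory Networks from Epigenomic Evidence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds context-specific gene regulatory networks for organisms
    with rich epigenomic data. A reference network is assembled by assigning
    transcription factors to the regulation of every gene whose transcription
    start site lies within a chosen upstream distance of one of the factor's
    binding sites, merged with experimentally determined miRNA-target edges.
    An ordered cascade of knowledge-based filters (DNA methylation, chromatin
    accessibility, histone marks, regulator expression, miRNA abundance) then
    removes regulations that are unlikely in the profiled condition and
    weights each surviving edge by the number of filters it passed. The
    package also constructs gold-standard networks from transcription factor
    ChIP-seq occupancy and compares networks at the level of single edges and
    of directed three-node graphlets (triads), globally and per node, with
    precision, recall and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    tools,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
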