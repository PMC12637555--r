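Package: piregulon
Title: Target-Centered Analysis of Pachytene piRNA Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies mRNAs targeted by swarms of antisense pachytene
    piRNAs, traces the targeting piRNAs back to their source piRNA clusters
    and embedded pseudogene fragments, and quantifies target derepression
    after pathway loss. Provides a near-match antisense scanner (one
    mismatch allowed across guide nucleotides 2-21), read-weighted target
    ranking, perfect-match genomic origin mapping with cluster attribution
    and one-to-one regulon calls, local-alignment based pseudogene-fragment
    discovery with target-site-duplication detection, positional nucleotide
    signatures (1U/10A), and ECDF/Kolmogorov-Smirnov comparison of
    expression fold changes. A synthetic-data generator emits genomes,
    annotations, piRNA libraries and count matrices with a machine-readable
    truth manifest so the entire pipeline can be exercised and validated
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
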