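Package: perinatmir
Title: Perinatal Tissue miRNA Expression Analysis with Synthetic Small RNA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An analysis toolkit for profiling microRNA expression across
    tissues around birth. Provides a synthetic small RNA-seq data generator
    with ground-truth tables; adapter trimming, read collapsing and
    mature-sequence quantification; annotation-class and genomic-context
    assignment for miRNA precursors; tissue-specificity scoring (TSI and an
    entropy-based specificity score); TMM-normalized negative-binomial exact
    tests for prenatal versus postnatal differential expression; cross-tissue
    overlap and direction-conservation analysis; canonical seed-site target
    prediction with hypergeometric gene-set enrichment and miRNA-mRNA network
    construction; and statistics for qRT-PCR (2^-ddCt), dual-luciferase and
    glucose-production assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
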