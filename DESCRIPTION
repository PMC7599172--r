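Package: tnverdict
Title: Gene Essentiality Inference from In Vivo Transposon Mutagenesis Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring gene essentiality in yeasts from in vivo
    transposon insertion sequencing (Tn-seq). Covers the full pipeline from
    transposon-tagged reads to per-ORF essentiality verdicts: tag trimming and
    junction calling, transposon target-motif scanning (TTAA, TnnnnA), library
    quality metrics and jackpot diagnostics, insertion-density feature
    engineering (Neighborhood Index, Freedom Index), Random-Forest
    classification with ROC/Youden threshold selection, ortholog-based
    training-set construction, cross-study transfer learning, and a synthetic
    genome/library simulator so every stage is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
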