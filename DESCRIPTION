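Package: txaxes
Title: Transcript-Resolution Lineage Specificity, RBP Regulation, and
    Drug-Association Axes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcript-resolution analysis of pan-cancer
    expression atlases: Shannon-entropy lineage-specificity scoring of
    transcripts across cell-line lineages, construction of high-confidence
    RNA-binding-protein (RBP) to transcript regulatory networks from
    knockdown differential expression and binding peaks, elastic-net
    regression with bootstrap sign-frequency scoring of transcript-drug
    sensitivity associations, relational integration into
    RBP-transcript-drug axes, a simplified junction-chain classifier for
    assembled transcripts against a reference annotation, and seeded
    synthetic-data generators with planted ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    glmnet,
    jsonlite,
    yaml,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
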