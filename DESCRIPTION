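Package: tzrsig
Title: Integrative Expression and Enhancer Analysis of Trastuzumab Resistance Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for identifying mRNAs and lincRNAs
    associated with trastuzumab resistance in HER2-positive breast cancer.
    Implements biotype-aware FPKM expression gating, fold-change and
    paired t-test differential-expression calling in tumor and cell-line
    modes, subtraction of short-term drug-response genes, concordant
    direction intersection of in vivo and in vitro gene sets with Fisher
    exact overlap enrichment, and enhancer-level ChIP signal log2-ratio
    summarization in 150-kb windows around transcription start sites.
    Ships a synthetic-data generator with planted ground truth so every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
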