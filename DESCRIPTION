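Package: hybridex
Title: Expression Inheritance and piRNA Ping-Pong Analysis for Reciprocal Hybrid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for ovarian transcriptomes of reciprocal
    interspecific Drosophila hybrids and their parental lines. Annotates
    de novo assembled transcriptome components against gene, genome and
    transposable-element references using identity/coverage thresholds;
    performs negative-binomial differential expression with median-of-ratios
    size-factor normalization and a joint FDR/fold-change significance rule;
    classifies genes and transposable elements into six expression-inheritance
    categories (conserved, additive, parent-dominant, over- and
    under-dominant); fits the nested mid-parent/half-difference linear model
    of hybrid expression; and detects piRNA ping-pong signatures from
    5-prime overlap histograms of mapped small RNAs. A synthetic-data
    generator with planted ground truth makes every stage testable without
    raw sequencing reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
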