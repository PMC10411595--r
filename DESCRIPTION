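Package: strainexpr
Title: Multi-Strain RNA-Seq Differential Expression with Reference-Bias
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of gene-expression variation across wild
    Caenorhabditis elegans strains under RNAi treatment. Provides
    negative binomial likelihood-ratio tests for strain and
    strain-by-treatment effects, within-strain RNAi contrasts with
    empirical-Bayes fold-change shrinkage, identification of
    strain-specific unexpressed ("off") genes, DNA-coverage-based
    screening for reference mapping bias, hypergeometric set-overlap
    enrichment, and a synthetic-data generator with ground-truth labels
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
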