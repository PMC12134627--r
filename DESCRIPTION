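Package: polysweep
Title: Selective-Sweep Scanning and Embryonic Time-Course Expression
    Analysis for Chicken Polydactyly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrated population-genomic and transcriptomic analysis of
    polydactyly in chicken. Implements two-tier variant filtering (GATK-style
    INFO hard filters, cohort call-rate/MAF/Hardy-Weinberg filters, proximity
    thinning), sliding-window nucleotide diversity and Hudson's Fst, joint
    top-quantile selective-sweep calling with region merging and gene ranking,
    a simplified ANNOVAR-style variant-effect classifier, TPM quantification
    with negative-binomial Wald differential expression, fuzzy c-means
    clustering of temporal expression profiles, hypergeometric gene-set
    over-representation, and Balding-Nichols / negative-binomial synthetic
    data generators that make every stage testable without raw sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite
Config/testthat/edition: 3
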