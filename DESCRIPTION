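Package: pleioGene
Title: Cross-Disorder Gene-Based Association, Meta-Analysis and Pleiotropy
    Classification from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based association testing from GWAS summary statistics using
    the mean chi-square statistic with a linkage-disequilibrium-aware null
    (eigenvalue-weighted sum of chi-squares, Imhof tail integration),
    competitive gene-set regression on probit-transformed gene p-values,
    pairwise sample-size-weighted Stouffer meta-analysis of gene Z-scores
    across disorders, summary-based transcriptome-wide association (TWAS)
    with greedy conditional analysis within loci, and classification of genes
    into shared, disorder-specific and novel-on-meta-analysis categories.
    Includes a synthetic-data generator that produces reference panels,
    paired disorder summary statistics with planted gene effects, gene sets
    with planted enrichment and sparse cis-eQTL weight models with known
    truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    data.table,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
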