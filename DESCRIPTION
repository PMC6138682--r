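Package: xscan
Title: Discovery of Autosomal Loci with Female-Specific Effects on
    X-Chromosome DNA Methylation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A mass-univariate meQTL discovery pipeline for autosomal
    genetic loci that alter DNA methylation across the X chromosome in a
    sex-specific way. Per-variant association with every X-chromosomal
    CpG is combined into one overall P-value with the Simes procedure
    (a global test), independent loci are identified by iterative
    conditional analysis, female-specificity is established against a
    male stratum including linkage-disequilibrium proxies, and loci are
    carried through genotype-by-sex interaction testing, multi-cohort
    Stouffer weighted-Z replication, cis-eQTL and trans-meQTL mapping,
    and enrichment testing against CpG-island and X-inactivation escape
    annotation. A synthetic-data generator with planted, recoverable
    ground truth exercises the pipeline end to end.
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
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
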