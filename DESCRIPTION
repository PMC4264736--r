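Package: xcisight
Title: X Chromosome Inactivation Ratio Estimation from Allele-Specific
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the X chromosome inactivation (XCI) ratio from
    allele-specific RNA-seq expression at heterozygous X-linked loci. Provides
    a haplotype-aware read and count simulator for in-silico benchmarking, a
    samtools-mpileup allele counter with the PAR/PASS/dbSNP/coverage filter
    cascade, a beta-distribution maximum-likelihood estimator for phased
    allelic ratios, a semiparametric two-component mixture estimator
    (stochastic EM) for unphased ratios, trio phase-by-transmission with
    out-of-phase hemizygous-deletion evidence, sliding-window log2 read-depth
    deletion detection, and classification of genes escaping XCI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    MASS,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
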