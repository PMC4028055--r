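Package: heritex
Title: Heritability and eQTL Mapping of Gene Expression in Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Variance-component (REML) estimation of narrow-sense heritability
    for replicated gene-expression traits in samples drawn from several
    geographically separated populations, using a merged block-diagonal kinship
    matrix estimated by method-of-moments IBD within each population.  Includes
    genotype quality control (call rate, minor allele frequency, Hardy-Weinberg,
    LD pruning), microarray-style expression normalisation (within-individual
    quantile normalisation, across-individual median normalisation, probe
    collapsing and replicate averaging), a structure-corrected genome-wide eQTL
    scan with Bonferroni thresholding, peak merging and cis/trans
    classification, eQTL heritability by variance-component differencing,
    SNP-by-SNP epistasis modelling with AIC selection, and midparent-offspring
    regression heritability for trio families.  A synthetic-data generator
    produces structured genotype panels (Balding-Nichols model), replicated
    expression phenotypes with configurable polygenic and QTL architecture, and
    trio families, so the whole analysis is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    ggplot2,
    withr
Config/testthat/edition: 3
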