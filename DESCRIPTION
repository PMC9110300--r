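Package: sibgwas
Title: Within-Sibship GWAS Estimation and Downstream Summary-Statistic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide association analysis in sibship cohorts.
    Fits population and within-sibship (family-mean-centered genotype)
    association models with sibship-clustered standard errors, standardizes
    and meta-analyzes study-level summary statistics, estimates the shrinkage
    of population relative to within-sibship effect estimates via weighted
    variant scores with jackknife standard errors and heterogeneity tests,
    provides a compact LD score regression for SNP heritability, confounding
    ratios and cross-trait genetic correlations with block-jackknife
    difference tests, runs inverse-variance-weighted Mendelian randomization
    with jackknife comparison of the two designs, and tests for polygenic
    adaptation by rank correlation of trait-aligned singleton density scores
    with association Z scores. Includes a family-cohort simulator that
    generates assortative mating, population stratification, parental and
    sibling indirect genetic effects, shared environment and cryptic
    relatedness, with truth tables for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
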