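Package: epipair
Title: Consensus Detection of Pairwise SNP-SNP Epistasis for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting and replicating pairwise statistical
    epistasis between biallelic SNPs and a quantitative trait such as body
    mass index. Provides readers for PLINK additive-recode (.raw) and VCF
    hard-call genotypes, variant quality control (Hardy-Weinberg exact test,
    call-rate and imputation-quality filters, distance-based locus pruning,
    stratum allele-frequency bias checks), closed-form pairwise interaction
    statistics (linear-regression interaction test, case/control allele-count
    odds-ratio Z test, two-locus ANOVA), multifactor dimensionality reduction
    (MDR) and its generalized score-based form (GMDR) with cross-validation
    consistency and testing balanced accuracy, permutation-based family-wise
    significance, consensus-across-methods and discovery-to-replication
    logic, genotype-combination prevalence analysis, and a configurable
    genotype-phenotype simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
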