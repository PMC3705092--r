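Package: survscan
Title: Candidate-Gene SNP Survival Scans with Max-T Permutation and
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Region-of-interest association analysis of SNP dosages with
    all-cause mortality: per-SNP additive Cox proportional-hazards scans
    adjusted for age and sex, genotype quality control (Hardy-Weinberg
    equilibrium, call rate, imputation R-squared, minor allele frequency),
    family-wise empirical significance by max-statistic phenotype
    permutation within gene regions, backward stepwise selection of
    independently associated SNPs, and fixed-effects inverse-variance
    meta-analysis across cohorts with direction-consistency summaries and
    Bonferroni verdicts. Includes a multi-cohort simulator (LD-structured
    haplotypes, imputation noise, Weibull proportional-hazards survival)
    so the whole pipeline is testable without individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
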