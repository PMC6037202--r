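Package: mptriage
Title: Germline Cancer-Predisposition Variant Triage for Multiple Primary Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Prioritization of germline variants in cancer-predisposition
    genes (CPGs) for cohorts of individuals with multiple primary tumors
    (MPTs). Implements an auditable small-variant filtering cascade
    (genotype quality, population frequency, truncating-consequence /
    ClinVar / HGMD / CADD retention rules, non-coding positional lookup,
    and five pathogenicity-refutation criteria), structural-variant
    prioritization from copy-number and breakend calls, combination of
    ACMG/AMP evidence codes into the five-tier classification, tumor
    phenotype-genotype concordance annotation, and cohort-level statistics
    (discordant tumor-combination analysis, registry comparison by
    uncorrected Pearson chi-squared tests, sex-adjusted reference
    population burden comparison, and diagnostic-yield projection). A
    seeded synthetic-data module generates complete cohort inputs with
    planted truth tables so every pipeline stage is testable without
    access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
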