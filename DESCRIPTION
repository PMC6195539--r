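Package: homburden
Title: Case-Control Homozygous Rare-Variant Burden Analysis with
    Gene-Set Resampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Collapsing analysis of homozygous rare variants in
    case-control exome cohorts. Implements genotype-level quality
    control (genotype quality, homozygous-call contamination,
    per-group missingness, indel exclusion), nested rarity/impact
    variant categories built from dataset and population minor allele
    frequencies and CADD scores, a subject-level homozygous-carrier
    burden test using the one-tailed Fisher exact test, an empirical
    null from random gene sets of matched size, exact and Monte Carlo
    power calculations for the Fisher test, and one-way ANOVA with
    Fisher's LSD post hoc from raw replicates or printed group
    summaries. A synthetic exome-cohort generator with Hardy-Weinberg
    genotypes, injected quality artefacts and optionally planted
    homozygous enrichment supports end-to-end testing without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, VariantAnnotation, StatisticalMethod, Software
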