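Package: prsphewas
Title: Polygenic Score Phenome-Wide Association Scanning with Pathway Partitioning
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for phenome-wide association analysis of
    polygenic risk scores (PRSs): variant quality control and allele-aware
    harmonization of external SNP weight files to genotype dosage data,
    raw and standardized score computation, linear-model association scans
    with a delta-adjusted-R2 effect measure and Benjamini-Hochberg q-values
    within per-score families, robust PRS-by-sex interaction tests,
    spline-based developmental trends of association strength with
    bootstrap confidence bands, and pathway-partitioned score construction
    via SNP-to-gene window mapping and hypergeometric over-representation.
    Includes a seeded synthetic-data generator (genotypes in Hardy-Weinberg
    proportions, sparse weights, longitudinal phenotypes with known
    variance explained, toy gene models and pathways) so that every stage
    has parameter-recovery tests without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1.0)
Imports:
    stats,
    utils,
    tools,
    splines,
    data.table,
    jsonlite,
    yaml,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
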