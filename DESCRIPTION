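Package: adiposePRS
Title: Unweighted Polygenic Risk Scores and Regional Adiposity Association Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of unweighted polygenic risk scores (PRS)
    for anthropometric and adiposity traits (body mass index, waist circumference,
    waist-hip ratio, body fat percentage) and their association with regional
    body-fat-distribution phenotypes (body fat percentage, subcutaneous and
    visceral adipose tissue volumes and their ratio). Provides imputed-dosage VCF
    input, variant quality control (minor allele frequency, call rate,
    Hardy-Weinberg equilibrium, imputation quality), greedy LD pruning with
    sentinel prioritization, an internal per-variant replication screen, rank-based
    inverse-normal transformation, ancestry principal components, covariate-adjusted
    linear and family random-intercept mixed models, Ward minimum-variance
    clustering of per-variant effect sizes, and a synthetic-cohort generator with a
    known multi-trait genetic architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    pheatmap,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, GenomeWideAssociationStudy, StatisticalMethod
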