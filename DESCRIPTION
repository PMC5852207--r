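Package: t1dgrs
Title: Type 1 Diabetes Genetic Risk Scoring with HLA Tag-SNP Imputation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes a log-additive type 1 diabetes genetic risk score (GRS)
    from risk-allele dosages, with tag-SNP imputation of the six
    HLA-DR3-DQ2/DR4-DQ8 diplotype categories and the DR15-DQ6, A24 and B57
    haplotypes. Provides the surrounding cohort machinery: genotype and
    metadata input with sample-level quality control, case-control odds
    ratios with Woolf confidence intervals and Fisher's exact tests,
    ROC/AUROC and balanced-accuracy threshold scanning, age-at-diagnosis
    association with prediction-band outlier detection, and a synthetic
    cohort generator (Hardy-Weinberg group-frequency mode and a liability
    threshold family mode) for end-to-end testing without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC
biocViews: GenomeWideAssociation, SNP, GeneticVariability, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
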