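Package: saavomics
Title: Proteogenomic SAAV Calling and Multi-Omics Integration for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds customized single-amino-acid-variant (SAAV) peptide
    databases from protein-level somatic variants by in-silico tryptic
    digestion of mutated sequences, calls SAAVs from peptide
    identification tables, classifies cohort specificity of variant
    sites, and integrates copy-number, mRNA and protein abundance with
    Spearman correlation, label-free differential-expression filtering
    (log2 median normalization, Welch tests with Benjamini-Hochberg
    correction and fold-change cutoffs) and Kaplan-Meier/log-rank
    survival stratification. Includes seeded generators that simulate
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
biocViews: Proteomics, Software, CopyNumberVariation, Survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
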