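Package: immunotype
Title: Immunogenomic Subtyping of Glioma Expression Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies bulk glioma expression cohorts into three ordered
    immune subtypes (immunity-high, immunity-medium, immunity-low) from
    single-sample gene-set enrichment (ssGSEA) profiles of 28 immune cell
    signatures. Provides rank-based ssGSEA scoring, signature-based immune
    and stromal scores with a cosine tumor-purity estimate, Ward
    hierarchical clustering with ordered subtype labels, cross-cohort
    Random Forest subtype prediction with accuracy and weighted F-score
    reports, MAF-derived tumor mutation burden and MATH intratumor
    heterogeneity, copy-number gain frequencies and group comparisons, a
    per-gene mutation-enrichment screen, Kaplan-Meier/log-rank survival
    comparisons, and a seeded synthetic-cohort generator with planted
    three-level immune structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Clustering, Classification,
    Survival, SomaticMutation, CopyNumberVariation
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'genomics.R'
    'immunotype-package.R'
    'io.R'
    'subtype.R'
    'scoring.R'
    'pipeline.R'
    'predict.R'
    'simulate.R'
    'stats.R'
    'utils.R'
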