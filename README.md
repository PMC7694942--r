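# immunotype

Immunogenomic subtyping of bulk glioma expression cohorts.

Gliomas differ widely in how strongly they are infiltrated by immune
cells, and that difference tracks with tumor grade, genomic instability
and patient survival. `immunotype` quantifies the immune contexture of
each tumor from bulk expression data, groups tumors into three ordered
immune subtypes, and characterizes the subtypes genomically and
clinically:

1. **ssGSEA scoring** — for each sample and immune gene set *S*, genes
   are ranked by expression and the enrichment score is the integrated
   difference between the weighted in-set cumulative distribution
   (weights *r*<sup>α</sup>, α = 0.25) and the uniform out-of-set
   distribution. The statistic is rank-based, hence invariant to
   monotone transforms of expression.
2. **Subtype discovery** — signature scores are Z-normalized per feature
   and clipped to ±3, samples are clustered with Ward's method
   (`ward.D2`, Euclidean) and the tree is cut at k = 3; clusters are
   labelled `immunity-high` / `immunity-medium` / `immunity-low` by
   decreasing mean enrichment.
3. **Cross-cohort prediction** — a 500-tree Random Forest trained on one
   cohort's features predicts subtypes in another, reported as a
   confusion matrix with accuracy and support-weighted F-score;
   stratified k-fold cross-validation with pooled out-of-fold scoring is
   also provided.
4. **Genomics** — tumor mutation burden (record counts), MATH intratumor
   heterogeneity (100 · 1.4826 · MAD/median of variant allele
   fractions), copy-number group comparisons, and a per-gene
   mutation-enrichment screen (Fisher test, Haldane-corrected odds
   ratio, Benjamini–Hochberg adjustment).
5. **Survival** — Kaplan–Meier curves and pairwise plus overall log-rank
   tests between subtypes.
6. **Synthetic cohorts** — a fully seeded generator plants the
   three-level immune structure together with matched mutation,
   copy-number and clinical data, so the whole pipeline can be validated
   end to end with known ground truth.

See `vignettes/immunotype-methods.Rmd` for the full methods description.

## Worked example

```r
library(immunotype)

spec   <- gliomaCohortSpec(seed = 1)      # 3 strata x 60 samples, 1500 genes
cohort <- generateCohort(spec)

# ssGSEA -> z-clip -> Ward clustering -> ordered labels
res <- subtypeCohort(cohort@expression, cohort@immuneSets)
table(subtypeLabels(res$subtypes), groundTruth(cohort))
#>                   high low medium
#>   immunity-high     60   0      0
#>   immunity-low       0  60      0
#>   immunity-medium    0   0     60

# Genomic characterization per subtype
gsum <- genomicSummary(cohort@mutations,
                       samples = sampleIDs(cohort@expression))
lab <- subtypeLabels(res$subtypes)[gsum$sample_id]
tapply(gsum$tmb, lab, median)
#>   immunity-high    immunity-low immunity-medium
#>            70.0            52.5            61.0
round(tapply(gsum$math_score, lab, median, na.rm = TRUE), 2)
#>   immunity-high    immunity-low immunity-medium
#>           27.15           41.34           33.39

# Survival differs between subtypes (immunity-high fares worst)
kmLogrank(cohort@clinical, res$subtypes)
#> Survival comparison (OS, time in months)
#>   overall log-rank: chisq = 15.3 (df 2), p = 0.000478
#>   immunity-high vs immunity-low: chisq = 12.1, p = 0.000506
#>   immunity-high vs immunity-medium: chisq = 0.0994, p = 0.753
#>   immunity-low vs immunity-medium: chisq = 7.99, p = 0.0047

# Subtypes transfer to an independent cohort
fit     <- trainSubtypeClassifier(res$features, res$subtypes, seed = 2)
cohort2 <- generateCohort(gliomaCohortSpec(seed = 3))
res2    <- subtypeCohort(cohort2@expression, cohort2@immuneSets)
crossCohortPredict(fit, res2$features, res2$subtypes)
#> ClassifierReport: accuracy 1.000, weighted F 1.000 (n = 180)
```

## Running the tests

From the repository root, with the package installed:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "immunotype", load_package = "installed")'
```

or interactively via `devtools::test()`.

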