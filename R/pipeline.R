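#' @include scoring.R subtype.R
NULL

#' Score, normalize and subtype one cohort
#'
#' Convenience wrapper running the per-cohort pipeline: ssGSEA scores for
#' the immune-cell sets, per-cohort Z-clip normalization, Ward hierarchical
#' clustering cut at k = 3 with ordered immunity labels. Each cohort is
#' processed independently (scores and Z normalization are never pooled
#' across cohorts).
#'
#' @param expr an [ExpressionMatrix-class].
#' @param immuneSets a [GeneSetList-class] of immune-cell signatures.
#' @param alpha ssGSEA rank-weight exponent.
#' @param normalize range-normalize the ssGSEA scores (see
#'   [ssgseaScores]).
#' @param linkage clustering linkage (see [clusterSubtypes]).
#' @return list with elements `scores` ([EnrichmentMatrix-class]),
#'   `features` ([NormalizedFeatureMatrix-class]) and `subtypes`
#'   ([SubtypeAssignment-class]).
#' @export
#' @examples
#' cohort <- generateCohort(gliomaCohortSpec(nPerStratum = c(8, 8, 8),
#'                                           nGenes = 400, seed = 3))
#' res <- subtypeCohort(cohort@expression, cohort@immuneSets)
#' table(subtypeLabels(res$subtypes), groundTruth(cohort))
subtypeCohort <- function(expr, immuneSets, alpha = 0.25,
                          normalize = TRUE, linkage = "ward") {
    sc <- ssgseaScores(expr, immuneSets, alpha = alpha,
                       normalize = normalize)
    feats <- zclipNormalize(sc)
    list(scores = sc, features = feats,
         subtypes = clusterSubtypes(feats, k = 3L, linkage = linkage))
}
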