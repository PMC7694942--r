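#' @include AllClasses.R AllGenerics.R
NULL

## ---- constructors ---------------------------------------------------------

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param logScale logical; are the values on log scale?
#' @param nDropped rows dropped at load time (bookkeeping).
#' @return An [ExpressionMatrix-class] object.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' ExpressionMatrix(m)
ExpressionMatrix <- function(values, logScale = TRUE, nDropped = 0L) {
    new("ExpressionMatrix", values = values, logScale = logScale,
        nDropped = as.integer(nDropped))
}

#' Construct a GeneSetList
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional character vector, one per set.
#' @return A [GeneSetList-class] object.
#' @export
GeneSetList <- function(sets, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- stats::setNames(rep("", length(sets)), names(sets))
    new("GeneSetList", sets = sets, descriptions = descriptions)
}

#' Construct a MutationTable from raw record fields
#'
#' VAF is computed as `alt/(ref+alt)`; records with zero total depth are
#' retained with `vaf_defined = FALSE`.
#'
#' @param sample_id,gene_symbol,variant_class character vectors.
#' @param ref_count,alt_count non-negative integer read counts.
#' @return A [MutationTable-class] object.
#' @export
MutationTable <- function(sample_id = character(), gene_symbol = character(),
                          variant_class = character(),
                          ref_count = integer(), alt_count = integer()) {
    depth <- ref_count + alt_count
    vaf <- ifelse(depth > 0, alt_count / depth, NA_real_)
    new("MutationTable", records = data.frame(
        sample_id = as.character(sample_id),
        gene_symbol = as.character(gene_symbol),
        variant_class = as.character(variant_class),
        ref_count = as.integer(ref_count),
        alt_count = as.integer(alt_count),
        vaf = vaf,
        vaf_defined = depth > 0,
        stringsAsFactors = FALSE))
}

#' Construct a CopyNumberTable
#'
#' @param calls integer matrix of thresholded calls in \{-2..2\},
#'   features x samples.
#' @param level `"gene"` or `"arm"`.
#' @return A [CopyNumberTable-class] object.
#' @export
CopyNumberTable <- function(calls, level = c("gene", "arm")) {
    level <- match.arg(level)
    storage.mode(calls) <- "integer"
    new("CopyNumberTable", level = level, calls = calls)
}

#' Construct a ClinicalTable
#'
#' @param data data.frame with columns `sample_id`, `survival_time`,
#'   `event_status`, `grade`, `idh_status`, `histology`.
#' @param timeUnit unit of the survival times (passed through, never
#'   converted).
#' @return A [ClinicalTable-class] object.
#' @export
ClinicalTable <- function(data, timeUnit = "months") {
    new("ClinicalTable", data = data, timeUnit = timeUnit)
}

## ---- accessors ------------------------------------------------------------

#' Accessors for pipeline containers
#'
#' `exprValues`, `geneIDs`, `sampleIDs` extract from an
#' [ExpressionMatrix-class]; `geneSets` and `signatureNames` from a
#' [GeneSetList-class]; `scores` from an [EnrichmentMatrix-class];
#' `subtypeLabels` from a [SubtypeAssignment-class]; `mutationRecords`,
#' `copyNumberCalls`, `clinicalData`, `featureValues`, `groundTruth` from
#' their respective classes.
#'
#' @param x the container object.
#' @return The underlying matrix, list, data.frame or vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("geneIDs", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetList", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("signatureNames", "GeneSetList", function(x) names(x@sets))

#' @rdname accessors
#' @export
setMethod("scores", "EnrichmentMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "EnrichmentMatrix", function(x) colnames(x@scores))

#' @rdname accessors
#' @export
setMethod("subtypeLabels", "SubtypeAssignment", function(x) {
    stats::setNames(as.character(x@assignment$label), x@assignment$sample_id)
})

#' @rdname accessors
#' @export
setMethod("sampleIDs", "SubtypeAssignment",
          function(x) x@assignment$sample_id)

#' @rdname accessors
#' @export
setMethod("mutationRecords", "MutationTable", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("copyNumberCalls", "CopyNumberTable", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("clinicalData", "ClinicalTable", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("featureValues", "NormalizedFeatureMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "NormalizedFeatureMatrix",
          function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticCohort", function(x) x@truth)

#' Subtype assignment as a data.frame
#'
#' @param x a [SubtypeAssignment-class].
#' @param row.names,optional,... passed through for the generic's signature;
#'   ignored.
#' @return data.frame with sample_id, label, cluster_index, ordering_key.
#' @export
as.data.frame.SubtypeAssignment <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
    x@assignment
}

## ---- show methods ---------------------------------------------------------

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale",
                nrow(object@values), ncol(object@values),
                if (object@logScale) "log" else "linear"))
    if (object@nDropped > 0L)
        cat(sprintf("; %d incomplete rows dropped at load", object@nDropped))
    cat(")\n")
})

setMethod("show", "GeneSetList", function(object) {
    sz <- vapply(object@sets, length, 1L)
    cat(sprintf("GeneSetList: %d sets", length(object@sets)))
    if (length(sz))
        cat(sprintf(" (sizes %d..%d)", min(sz), max(sz)))
    cat("\n")
})

setMethod("show", "EnrichmentMatrix", function(object) {
    cat(sprintf("EnrichmentMatrix: %d sets x %d samples (%s, alpha = %g)\n",
                nrow(object@scores), ncol(object@scores),
                object@normalization, object@alpha))
})

setMethod("show", "SubtypeAssignment", function(object) {
    tab <- table(object@assignment$label)
    cat("SubtypeAssignment:",
        paste(sprintf("%s = %d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
})

setMethod("show", "MutationTable", function(object) {
    r <- object@records
    cat(sprintf(
        "MutationTable: %d records, %d samples, %d genes (%d VAF-defined)\n",
        nrow(r), length(unique(r$sample_id)), length(unique(r$gene_symbol)),
        sum(r$vaf_defined)))
})

setMethod("show", "CopyNumberTable", function(object) {
    cat(sprintf("CopyNumberTable (%s-level): %d features x %d samples\n",
                object@level, nrow(object@calls), ncol(object@calls)))
})

setMethod("show", "ClinicalTable", function(object) {
    d <- object@data
    cat(sprintf("ClinicalTable: %d samples, %d events (time in %s)\n",
                nrow(d), sum(d$event_status, na.rm = TRUE), object@timeUnit))
})

setMethod("show", "ClassifierReport", function(object) {
    cat(sprintf("ClassifierReport: accuracy %.3f, weighted F %.3f (n = %d)\n",
                object@accuracy, object@weightedF, sum(object@confusion)))
})

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf(
        "CohortSpec: %d genes, n = %s per stratum, delta = (%s), seed %d\n",
        object@nGenes, paste(object@nPerStratum, collapse = "/"),
        paste(object@delta, collapse = ", "), object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort\n")
    cat("  "); show(object@expression)
    cat("  "); show(object@mutations)
    cat("  "); show(object@clinical)
    cat(sprintf("  planted strata: %s\n",
                paste(sprintf("%s = %d", names(table(object@truth)),
                              as.integer(table(object@truth))),
                      collapse = ", ")))
})
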