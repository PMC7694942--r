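#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core containers. All heavy tables are plain matrices / data.frames wrapped
## in thin S4 classes whose validity methods enforce the pipeline's contracts,
## so downstream code never re-checks inputs.
## ---------------------------------------------------------------------------

#' ExpressionMatrix: genes x samples expression values
#'
#' Container for a bulk expression matrix (rows = gene symbols, columns =
#' sample identifiers). Values are assumed to be on log scale unless
#' `logScale = FALSE`; no transform is applied on construction.
#'
#' @slot values numeric matrix, genes x samples, with unique dimnames and no
#'   missing values.
#' @slot logScale logical flag; `TRUE` means values are log-scale.
#' @slot nDropped number of input rows dropped for missing values at load.
#'
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(values = "matrix", logScale = "logical",
                   nDropped = "integer"),
    prototype(logScale = TRUE, nDropped = 0L))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "expression values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "expression matrix must carry gene and sample names")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, "duplicate gene ids")
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, "duplicate sample ids")
    }
    if (nrow(v) < 2L || ncol(v) < 2L)
        msg <- c(msg, "need at least 2 genes and 2 samples")
    if (anyNA(v))
        msg <- c(msg, "missing values present after load")
    if (length(msg)) msg else TRUE
})

#' GeneSetList: named collection of gene signatures
#'
#' @slot sets named list; each element a character vector of unique gene
#'   symbols.
#' @slot descriptions named character vector, one per set (may be empty
#'   strings).
#'
#' @aliases GeneSetList-class
#' @exportClass GeneSetList
setClass("GeneSetList",
    representation(sets = "list", descriptions = "character"))

setValidity("GeneSetList", function(object) {
    s <- object@sets
    msg <- character()
    if (length(s)) {
        if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
            msg <- c(msg, "set names must be unique and non-empty")
        if (any(vapply(s, length, 1L) == 0L))
            msg <- c(msg, "empty gene set")
        if (any(vapply(s, anyDuplicated, 1L) > 0L))
            msg <- c(msg, "duplicate genes within a set")
    }
    if (length(object@descriptions) != length(s))
        msg <- c(msg, "one description per set required")
    if (length(msg)) msg else TRUE
})

#' EnrichmentMatrix: gene-set x sample enrichment scores
#'
#' @slot scores numeric matrix, sets x samples.
#' @slot normalization `"raw"` or `"range"` (range-rescaled to \[0, 1\] over
#'   the whole collection).
#' @slot alpha rank-weighting exponent used to compute the scores.
#'
#' @aliases EnrichmentMatrix-class
#' @exportClass EnrichmentMatrix
setClass("EnrichmentMatrix",
    representation(scores = "matrix", normalization = "character",
                   alpha = "numeric"))

setValidity("EnrichmentMatrix", function(object) {
    msg <- character()
    if (!object@normalization %in% c("raw", "range"))
        msg <- c(msg, "normalization must be 'raw' or 'range'")
    if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
        msg <- c(msg, "scores must carry set and sample names")
    if (length(msg)) msg else TRUE
})

#' SubtypeAssignment: ordered immune subtype labels per sample
#'
#' Labels are `immunity-high` / `immunity-medium` / `immunity-low`, ordered by
#' descending cluster-mean normalized enrichment (the `ordering_key` column).
#'
#' @slot assignment data.frame with columns `sample_id`, `label` (factor with
#'   the three ordered levels), `cluster_index` (raw dendrogram cut id) and
#'   `ordering_key` (cluster mean feature Z).
#'
#' @aliases SubtypeAssignment-class
#' @exportClass SubtypeAssignment
setClass("SubtypeAssignment",
    representation(assignment = "data.frame"))

subtypeLevels <- c("immunity-high", "immunity-medium", "immunity-low")

setValidity("SubtypeAssignment", function(object) {
    a <- object@assignment
    msg <- character()
    need <- c("sample_id", "label", "cluster_index", "ordering_key")
    if (!all(need %in% names(a)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, names(a)), collapse = ", ")))
    else {
        if (anyDuplicated(a$sample_id))
            msg <- c(msg, "duplicate sample ids")
        ok3 <- identical(levels(a$label), subtypeLevels)
        okK <- all(grepl("^cluster-", levels(a$label)))
        if (!is.factor(a$label) || !(ok3 || okK))
            msg <- c(msg, "label must be a factor over the three ordered subtypes")
    }
    if (length(msg)) msg else TRUE
})

#' NormalizedFeatureMatrix: Z-scored, clipped feature matrix
#'
#' Features x samples matrix where each feature has been Z-scored across
#' samples (sample sd, n-1 denominator) and clipped to \[-3, 3\].
#'
#' @slot values numeric matrix in \[-3, 3\].
#' @slot droppedFeatures features removed for zero variance.
#'
#' @aliases NormalizedFeatureMatrix-class
#' @exportClass NormalizedFeatureMatrix
setClass("NormalizedFeatureMatrix",
    representation(values = "matrix", droppedFeatures = "character"))

setValidity("NormalizedFeatureMatrix", function(object) {
    v <- object@values
    if (length(v) && (min(v) < -3 || max(v) > 3))
        "values must lie in [-3, 3]" else TRUE
})

#' MutationTable: per-variant somatic mutation records
#'
#' @slot records data.frame with columns `sample_id`, `gene_symbol`,
#'   `variant_class`, `ref_count`, `alt_count`, `vaf`, `vaf_defined`.
#'   `vaf` is `alt/(ref+alt)`, `NA` (and `vaf_defined = FALSE`) when
#'   `ref + alt == 0`.
#'
#' @aliases MutationTable-class
#' @exportClass MutationTable
setClass("MutationTable", representation(records = "data.frame"))

setValidity("MutationTable", function(object) {
    r <- object@records
    msg <- character()
    need <- c("sample_id", "gene_symbol", "variant_class",
              "ref_count", "alt_count", "vaf", "vaf_defined")
    if (!all(need %in% names(r)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, names(r)), collapse = ", ")))
    else if (nrow(r)) {
        if (any(r$ref_count < 0 | r$alt_count < 0))
            msg <- c(msg, "negative read counts")
        if (any(!nzchar(r$sample_id)) || any(!nzchar(r$gene_symbol)))
            msg <- c(msg, "empty sample or gene symbol")
    }
    if (length(msg)) msg else TRUE
})

#' CopyNumberTable: thresholded copy-number calls
#'
#' Gene- or arm-level integer calls in \{-2, -1, 0, 1, 2\} (GISTIC-style
#' thresholded layout), features x samples.
#'
#' @slot level `"gene"` or `"arm"`.
#' @slot calls integer matrix, features x samples.
#'
#' @aliases CopyNumberTable-class
#' @exportClass CopyNumberTable
setClass("CopyNumberTable",
    representation(level = "character", calls = "matrix"))

setValidity("CopyNumberTable", function(object) {
    msg <- character()
    if (!object@level %in% c("gene", "arm"))
        msg <- c(msg, "level must be 'gene' or 'arm'")
    cl <- object@calls
    if (length(cl)) {
        if (!all(cl %in% -2:2))
            msg <- c(msg, "calls must lie in {-2,-1,0,1,2}")
        if (is.null(rownames(cl)) || anyDuplicated(rownames(cl)))
            msg <- c(msg, "feature ids must be present and unique")
    }
    if (length(msg)) msg else TRUE
})

#' ClinicalTable: per-sample clinical annotations
#'
#' @slot data data.frame with columns `sample_id`, `survival_time`,
#'   `event_status` (0/1 or NA), `grade` (`"II"`, `"III"`, `"IV"` or NA),
#'   `idh_status` (`"mutant"`, `"wildtype"` or NA), `histology`.
#' @slot timeUnit unit of `survival_time` (e.g. `"days"`, `"months"`); passed
#'   through unconverted.
#'
#' @aliases ClinicalTable-class
#' @exportClass ClinicalTable
setClass("ClinicalTable",
    representation(data = "data.frame", timeUnit = "character"))

setValidity("ClinicalTable", function(object) {
    d <- object@data
    msg <- character()
    need <- c("sample_id", "survival_time", "event_status", "grade",
              "idh_status", "histology")
    if (!all(need %in% names(d)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, names(d)), collapse = ", ")))
    else if (nrow(d)) {
        ev <- d$event_status[!is.na(d$event_status)]
        if (!all(ev %in% c(0, 1)))
            msg <- c(msg, "event_status must be 0/1")
        if (any(!is.na(d$event_status) & is.na(d$survival_time)))
            msg <- c(msg, "survival_time required wherever event_status present")
        st <- d$survival_time[!is.na(d$survival_time)]
        if (any(st < 0))
            msg <- c(msg, "negative survival_time")
    }
    if (length(msg)) msg else TRUE
})

#' ClassifierReport: evaluation of a subtype classifier
#'
#' @slot accuracy overall accuracy in \[0, 1\].
#' @slot weightedF support-weighted mean of per-class F1 scores.
#' @slot perClass data.frame with per-class precision, recall, F1, support.
#' @slot confusion integer matrix, rows = true class, columns = predicted.
#' @slot importance named numeric vector of feature importances (mean
#'   impurity decrease), empty when not applicable.
#' @slot trainCohort identifier of the training cohort.
#' @slot seed RNG seed used for training/fold assignment.
#'
#' @aliases ClassifierReport-class
#' @exportClass ClassifierReport
setClass("ClassifierReport",
    representation(accuracy = "numeric", weightedF = "numeric",
                   perClass = "data.frame", confusion = "matrix",
                   importance = "numeric", trainCohort = "character",
                   seed = "integer"))

setValidity("ClassifierReport", function(object) {
    msg <- character()
    cm <- object@confusion
    if (length(cm)) {
        if (!isTRUE(all.equal(unname(rowSums(cm)),
                              as.numeric(object@perClass$support))))
            msg <- c(msg, "confusion row sums must equal class supports")
        acc <- sum(diag(cm)) / sum(cm)
        if (abs(acc - object@accuracy) > 1e-12)
            msg <- c(msg, "accuracy must equal trace/total")
    }
    if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Defines the planted three-level immune structure: per-stratum expression
#' shifts on immune-set genes, mutation burden, VAF dispersion, copy-number
#' alteration rates, survival hazards and clinical label frequencies. Strata
#' are ordered high, medium, low throughout; every per-stratum slot is a
#' length-3 vector in that order.
#'
#' @slot nGenes total number of genes in the expression matrix.
#' @slot nPerStratum samples per stratum (high, medium, low).
#' @slot nImmuneSets number of immune-cell signatures (28 in the standard
#'   panel).
#' @slot setSize genes per immune signature (sets sampled disjoint by
#'   default).
#' @slot setOverlap fraction of each set's genes shared with a common pool
#'   (0 = fully disjoint).
#' @slot delta per-stratum expression shift on immune-set genes, in units of
#'   the noise sd; must be strictly decreasing high > medium > low.
#' @slot noiseSD sd of the baseline log-expression noise.
#' @slot promotingBoost,inhibitingBoost multipliers applied to `delta` for
#'   the immune-promoting and immune-inhibiting marker sets (drives the
#'   signature-ratio ordering).
#' @slot tmbMean per-stratum Poisson mean of the somatic mutation count.
#' @slot vafMean,vafConcentration per-stratum Beta mean and concentration of
#'   the variant allele fractions (dispersion = mean(1-mean)/(1+conc)).
#' @slot armGainProb,armLossProb per-stratum per-arm Bernoulli rates of
#'   thresholded gain / loss calls.
#' @slot nArms number of chromosome arms simulated.
#' @slot geneGainProb per-stratum gain rate for the cytokine-like gene panel
#'   in the gene-level copy-number table.
#' @slot hazard per-stratum exponential survival hazard (per month).
#' @slot censorFraction fraction of samples uniformly right-censored.
#' @slot gradeIVProb,idhMutantProb per-stratum Bernoulli rates for grade IV
#'   histology and IDH-mutant status.
#' @slot enrichedGeneProb per-stratum mutation probability of each planted
#'   screen-enrichment gene.
#' @slot nEnrichedGenes number of planted screen-enrichment genes.
#' @slot nBackgroundGenes size of the background mutated-gene pool.
#' @slot seed integer RNG seed; all randomness flows from it.
#'
#' @aliases CohortSpec-class
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(nGenes = "integer", nPerStratum = "integer",
                   nImmuneSets = "integer", setSize = "integer",
                   setOverlap = "numeric",
                   delta = "numeric", noiseSD = "numeric",
                   promotingBoost = "numeric", inhibitingBoost = "numeric",
                   tmbMean = "numeric", vafMean = "numeric",
                   vafConcentration = "numeric",
                   armGainProb = "numeric", armLossProb = "numeric",
                   nArms = "integer", geneGainProb = "numeric",
                   hazard = "numeric", censorFraction = "numeric",
                   gradeIVProb = "numeric", idhMutantProb = "numeric",
                   enrichedGeneProb = "numeric", nEnrichedGenes = "integer",
                   nBackgroundGenes = "integer", seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    len3 <- c("nPerStratum", "delta", "tmbMean", "vafMean",
              "vafConcentration", "armGainProb", "armLossProb",
              "geneGainProb", "hazard", "gradeIVProb", "idhMutantProb",
              "enrichedGeneProb")
    for (s in len3)
        if (length(slot(object, s)) != 3L)
            msg <- c(msg, paste0(s, " must have length 3 (high, medium, low)"))
    ## non-increasing (ties allowed so the no-signal null cohort is
    ## expressible; the default is strictly decreasing)
    if (length(object@delta) == 3L && any(diff(object@delta) > 0))
        msg <- c(msg, "delta must be non-increasing high >= medium >= low")
    probs <- c(object@armGainProb, object@armLossProb, object@geneGainProb,
               object@gradeIVProb, object@idhMutantProb,
               object@enrichedGeneProb, object@censorFraction,
               object@setOverlap)
    if (length(probs) && (any(probs < 0) || any(probs > 1)))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (any(object@hazard <= 0))
        msg <- c(msg, "hazards must be positive")
    if (any(object@vafMean <= 0 | object@vafMean >= 1))
        msg <- c(msg, "vafMean must lie in (0, 1)")
    ## immune sets + stromal (2 x setSize) + 4 marker sets + PD-L1 gene
    ## are all drawn from the expression gene pool
    needed <- object@nImmuneSets * object@setSize +
        6L * object@setSize + 1L
    if (length(needed) && !is.na(needed) && needed > object@nGenes)
        msg <- c(msg, "gene-set request exceeds nGenes")
    if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a fully linked synthetic glioma cohort
#'
#' Bundles every input the pipeline consumes — expression, immune gene sets,
#' signature sets, mutations, copy number, clinical annotations — plus the
#' ground-truth stratum of each sample, kept separate from the analysis
#' inputs.
#'
#' @slot expression ExpressionMatrix (log-scale).
#' @slot immuneSets GeneSetList of the immune-cell signatures.
#' @slot signatures GeneSetList of auxiliary signatures (immune/stromal
#'   score sets, promoting/inhibiting marker pairs, PD-L1-like marker).
#' @slot mutations MutationTable.
#' @slot copyNumber gene-level CopyNumberTable.
#' @slot armCalls arm-level CopyNumberTable.
#' @slot clinical ClinicalTable.
#' @slot truth named character vector: planted stratum
#'   (`"high"`/`"medium"`/`"low"`) per sample.
#' @slot spec the CohortSpec that generated the cohort.
#'
#' @aliases SyntheticCohort-class
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
    representation(expression = "ExpressionMatrix",
                   immuneSets = "GeneSetList",
                   signatures = "GeneSetList",
                   mutations = "MutationTable",
                   copyNumber = "CopyNumberTable",
                   armCalls = "CopyNumberTable",
                   clinical = "ClinicalTable",
                   truth = "character",
                   spec = "CohortSpec"))

setValidity("SyntheticCohort", function(object) {
    ids <- colnames(object@expression@values)
    msg <- character()
    if (!setequal(ids, object@clinical@data$sample_id))
        msg <- c(msg, "clinical samples must match expression samples")
    if (!setequal(ids, names(object@truth)))
        msg <- c(msg, "truth labels must cover all samples")
    if (length(object@armCalls@calls) &&
        !setequal(ids, colnames(object@armCalls@calls)))
        msg <- c(msg, "arm-call samples must match expression samples")
    if (length(msg)) msg else TRUE
})
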