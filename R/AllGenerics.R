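#' @include AllClasses.R
NULL

#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))

#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' @export
setGeneric("mutationRecords", function(x) standardGeneric("mutationRecords"))

#' @export
setGeneric("copyNumberCalls", function(x) standardGeneric("copyNumberCalls"))

#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
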