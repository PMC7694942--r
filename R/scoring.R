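#' @include AllClasses.R accessors.R
NULL

## ---------------------------------------------------------------------------
## Single-sample gene-set enrichment (ssGSEA).
##
## For one sample: genes are walked in decreasing-expression order. The
## in-set cumulative fraction accumulates rank weights r^alpha (r = average
## rank within the sample, largest expression = N), normalized by their
## total; the out-of-set fraction accumulates uniformly. The enrichment
## score is the sum over all walk positions of (in-set - out-of-set)
## cumulative fractions. Ties in the walk order are broken by input gene
## order (order() is stable), so scoring is deterministic.
## ---------------------------------------------------------------------------

ssgseaOneSample <- function(x, setIndicator, alpha) {
    N <- length(x)
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    w <- r^alpha
    ind <- setIndicator[ord, , drop = FALSE]
    wOrd <- w[ord]
    inCum <- apply(ind * wOrd, 2L, cumsum)
    inTot <- colSums(setIndicator * w)
    outCum <- apply(!ind, 2L, cumsum)
    outTot <- N - colSums(setIndicator)
    colSums(t(t(inCum) / inTot) - t(t(outCum) / outTot))
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Computes, for every gene set and sample, a rank-based running-sum
#' enrichment score quantifying how coordinately the set's genes are up- or
#' down-regulated within that sample. Scores are rank-based, hence invariant
#' to any strictly monotone transform of a sample's expression vector.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param sets a [GeneSetList-class]; each set is intersected with the
#'   matrix's genes first. A set with no overlap gets `NA` scores (with a
#'   warning); a set covering every gene is an error (the out-of-set
#'   fraction is undefined).
#' @param alpha rank-weighting exponent (>= 0). `alpha = 0` gives the
#'   unweighted Kolmogorov running sum; the default 0.25 is the method's
#'   conventional choice.
#' @param normalize if `TRUE` (default), scores are linearly rescaled to
#'   \[0, 1\] by the global minimum and maximum across all sets and samples
#'   of the collection; `FALSE` returns the raw running-sum totals.
#' @return An [EnrichmentMatrix-class], sets x samples.
#' @export
#' @examples
#' m <- matrix(c(4, 3, 2, 1, 1, 3, 2, 4), ncol = 2,
#'             dimnames = list(paste0("g", 1:4), c("s1", "s2")))
#' sets <- GeneSetList(list(S1 = c("g1", "g2")))
#' scores(ssgseaScores(ExpressionMatrix(m), sets, normalize = FALSE))
ssgseaScores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
    stopifnot(alpha >= 0)
    v <- exprValues(expr)
    genes <- rownames(v)
    setList <- geneSets(sets)
    overlap <- lapply(setList, intersect, x = genes)
    nOv <- lengths(overlap)
    if (any(nOv == length(genes)))
        stop("gene set(s) covering ALL genes: ",
             paste(names(setList)[nOv == length(genes)], collapse = ", "),
             " (out-of-set fraction undefined)")
    empty <- nOv == 0L
    if (any(empty))
        warning("set(s) with no gene overlap scored as NA: ",
                paste(names(setList)[empty], collapse = ", "))
    usable <- which(!empty)
    ind <- matrix(FALSE, length(genes), length(usable),
                  dimnames = list(genes, names(setList)[usable]))
    for (j in seq_along(usable))
        ind[overlap[[usable[j]]], j] <- TRUE
    es <- matrix(NA_real_, length(setList), ncol(v),
                 dimnames = list(names(setList), colnames(v)))
    if (length(usable))
        es[usable, ] <- vapply(seq_len(ncol(v)),
                               function(i) ssgseaOneSample(v[, i], ind, alpha),
                               numeric(length(usable)))
    normalization <- "raw"
    if (normalize) {
        rng <- range(es, na.rm = TRUE)
        es <- if (rng[2] > rng[1]) (es - rng[1]) / (rng[2] - rng[1])
              else es * 0
        normalization <- "range"
    }
    new("EnrichmentMatrix", scores = es, normalization = normalization,
        alpha = alpha)
}

## Tumor purity anchor: cosine link between the combined immune+stromal
## score and the malignant-cell fraction.
purityIntercept <- 0.6049872018
puritySlope <- 0.0001467884

#' Immune score, stromal score and tumor purity
#'
#' Scores the immune and stromal signatures by raw ssGSEA (the signature
#' scores are used directly, unscaled), sums them into a combined score, and
#' maps that to an estimated tumor purity via
#' `purity = cos(0.6049872018 + 0.0001467884 * combined)`. Purity is
#' monotonically decreasing in the combined score on the reported domain;
#' the `purity` column is clipped to \[0, 1\] with the raw cosine kept in
#' `purity_raw`.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param immuneSig,stromalSig [GeneSetList-class] objects each holding one
#'   signature (the first set is used). The package ships small synthetic
#'   demonstration signatures (see [syntheticEstimateSignatures]); for real
#'   cohorts supply the published immune/stromal signature gene lists.
#' @param alpha rank-weighting exponent passed to [ssgseaScores].
#' @return data.frame with columns `sample_id`, `immune_score`,
#'   `stromal_score`, `estimate_score` (= immune + stromal), `purity_raw`
#'   and `purity`.
#' @export
estimateScores <- function(expr, immuneSig, stromalSig, alpha = 0.25) {
    sigs <- GeneSetList(list(immune = geneSets(immuneSig)[[1L]],
                             stromal = geneSets(stromalSig)[[1L]]))
    genes <- geneIDs(expr)
    if (!length(intersect(sigs@sets$immune, genes)) ||
        !length(intersect(sigs@sets$stromal, genes)))
        stop("immune/stromal signature has no overlap with the expression matrix")
    es <- scores(ssgseaScores(expr, sigs, alpha = alpha, normalize = FALSE))
    combined <- es["immune", ] + es["stromal", ]
    purityRaw <- cos(purityIntercept + puritySlope * combined)
    data.frame(sample_id = colnames(es),
               immune_score = unname(es["immune", ]),
               stromal_score = unname(es["stromal", ]),
               estimate_score = unname(combined),
               purity_raw = unname(purityRaw),
               purity = pmin(pmax(unname(purityRaw), 0), 1),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Log2 ratio of two immune signatures
#'
#' Per sample, the base-2 log of the quotient of the mean linear-scale
#' expression of the first signature's marker genes over the second's
#' (e.g. CD8+ effector / regulatory T cells, M1 / M2 macrophages). The
#' ratio is antisymmetric: swapping the signatures negates it.
#'
#' @param expr an [ExpressionMatrix-class]. If declared log-scale, values
#'   are exponentiated (base 2) before averaging; means must be positive.
#' @param sigA,sigB character vectors of marker gene symbols (>= 1 present
#'   in the matrix).
#' @param name label for the signature pair.
#' @return data.frame with columns `sample_id`, `ratio` and attribute
#'   `pair`.
#' @export
signatureRatio <- function(expr, sigA, sigB, name = "A/B") {
    v <- exprValues(expr)
    if (expr@logScale) v <- 2^v
    gA <- intersect(sigA, rownames(v))
    gB <- intersect(sigB, rownames(v))
    if (!length(gA) || !length(gB))
        stop("both signatures need >= 1 gene present in the matrix")
    mA <- colMeans(v[gA, , drop = FALSE])
    mB <- colMeans(v[gB, , drop = FALSE])
    if (any(mA <= 0) || any(mB <= 0))
        stop("non-positive signature mean; supply linear-scale expression ",
             "(or a correctly declared log-scale matrix)")
    out <- data.frame(sample_id = colnames(v),
                      ratio = unname(log2(mA) - log2(mB)),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "pair") <- name
    out
}
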