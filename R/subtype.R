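#' @include AllClasses.R accessors.R
NULL

#' Z-score and clip enrichment features
#'
#' Per feature (row), values are Z-scored across samples using the sample
#' standard deviation (n - 1 denominator) and then clipped to \[-3, 3\]:
#' any Z above 3 becomes 3, any Z below -3 becomes -3. Zero-variance
#' features are dropped with a warning; a single-sample matrix is an error
#' (Z undefined).
#'
#' @param x an [EnrichmentMatrix-class] or a numeric features x samples
#'   matrix.
#' @return A [NormalizedFeatureMatrix-class].
#' @export
zclipNormalize <- function(x) {
    v <- if (is(x, "EnrichmentMatrix")) scores(x) else x
    if (ncol(v) < 2L)
        stop("Z normalization needs >= 2 samples")
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    constant <- sdv == 0 | is.na(sdv)
    dropped <- rownames(v)[constant]
    if (any(constant)) {
        warning("dropping zero-variance feature(s): ",
                paste(dropped, collapse = ", "))
        v <- v[!constant, , drop = FALSE]
        mu <- mu[!constant]
        sdv <- sdv[!constant]
    }
    z <- (v - mu) / sdv
    z[z > 3] <- 3
    z[z < -3] <- -3
    new("NormalizedFeatureMatrix", values = z, droppedFeatures = dropped)
}

#' Hierarchical clustering into ordered immune subtypes
#'
#' Agglomerative hierarchical clustering of samples on their normalized
#' immune-cell enrichment profiles (Euclidean distance, Ward linkage by
#' default), cut into `k` clusters. Clusters are then ordered by their mean
#' normalized enrichment across all features and labelled
#' `immunity-high` > `immunity-medium` > `immunity-low` in descending order
#' of that key. The assignment is invariant to sample order.
#'
#' @param features a [NormalizedFeatureMatrix-class] (features x samples),
#'   typically [zclipNormalize] applied to the 28 immune-cell ssGSEA
#'   scores.
#' @param k number of clusters (fixed at 3 for the immune subtyping).
#' @param linkage `"ward"` (Ward on squared Euclidean via `ward.D2`),
#'   `"complete"` or `"average"`.
#' @return A [SubtypeAssignment-class].
#' @export
clusterSubtypes <- function(features, k = 3L,
                            linkage = c("ward", "complete", "average")) {
    linkage <- match.arg(linkage)
    v <- featureValues(features)
    n <- ncol(v)
    if (n < k)
        stop("need at least k = ", k, " samples, got ", n)
    method <- c(ward = "ward.D2", complete = "complete",
                average = "average")[[linkage]]
    ## cluster on a canonical sample order so the tree (and hence the cut)
    ## does not depend on input column order
    canon <- order(colnames(v))
    hc <- stats::hclust(stats::dist(t(v[, canon, drop = FALSE])),
                        method = method)
    cutCanon <- stats::cutree(hc, k = k)
    cut <- cutCanon[match(colnames(v), colnames(v)[canon])]
    names(cut) <- colnames(v)
    stopifnot(length(unique(cut)) == k)
    key <- vapply(seq_len(k),
                  function(cl) mean(v[, cut == cl, drop = FALSE]),
                  numeric(1))
    ord <- order(key, seq_len(k), decreasing = c(TRUE, FALSE),
                 method = "radix")
    labelOf <- character(k)
    lv <- if (k == 3L) subtypeLevels
          else paste0("cluster-", seq_len(k))
    labelOf[ord] <- lv
    assignment <- data.frame(
        sample_id = colnames(v),
        label = factor(labelOf[cut], levels = lv),
        cluster_index = as.integer(cut),
        ordering_key = key[cut],
        stringsAsFactors = FALSE, row.names = NULL)
    new("SubtypeAssignment", assignment = assignment)
}

#' Split samples into score tertiles
#'
#' Ranks samples on a per-sample score and assigns the top `ceiling(n/3)` to
#' the high third, the bottom `ceiling(n/3)` to the low third, and the rest
#' to the middle. Ties at the boundaries are resolved by stable rank order
#' (input order among equal values); an all-equal vector splits by input
#' order with a warning.
#'
#' @param x named numeric vector of per-sample scores (n >= 3).
#' @return factor over `"high-third"`, `"middle"`, `"low-third"`, named by
#'   sample.
#' @export
tertileSplit <- function(x) {
    n <- length(x)
    if (n < 3L)
        stop("tertile split needs >= 3 samples")
    if (length(unique(x)) == 1L)
        warning("all scores equal; splitting by stable input order")
    nT <- ceiling(n / 3)
    ord <- order(x, decreasing = TRUE)  # stable: ties keep input order
    g <- rep("middle", n)
    g[ord[seq_len(nT)]] <- "high-third"
    g[ord[seq.int(n, n - nT + 1L)]] <- "low-third"
    stats::setNames(factor(g, levels = c("high-third", "middle",
                                         "low-third")),
                    names(x))
}
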