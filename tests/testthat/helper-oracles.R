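# Independent oracles, written as plain step-by-step loops so they share no
# code path with the package implementations they check.

# ssGSEA: explicit walk in decreasing-expression order, in-set cumulative
# weight r^alpha vs uniform out-of-set cumulative fraction.
ssgseaOracle <- function(x, setGenes, alpha) {
    genes <- names(x)
    r <- rank(x, ties.method = "average")
    walk <- genes[order(x, decreasing = TRUE)]
    inset <- walk %in% setGenes
    wtot <- sum(r[setGenes]^alpha)
    nout <- sum(!(genes %in% setGenes))
    pin <- 0; pout <- 0; es <- 0
    for (i in seq_along(walk)) {
        if (inset[i]) pin <- pin + r[[walk[i]]]^alpha / wtot
        else pout <- pout + 1 / nout
        es <- es + (pin - pout)
    }
    unname(es)
}

# MATH: literal median / scaled-MAD formula.
mathOracle <- function(v) {
    med <- median(v)
    100 * (1.4826 * median(abs(v - med))) / med
}

# Weighted F from a confusion matrix, per-class loop.
weightedFOracle <- function(cm) {
    total <- 0; wsum <- 0
    for (c in seq_len(nrow(cm))) {
        support <- sum(cm[c, ])
        prec <- if (sum(cm[, c]) > 0) cm[c, c] / sum(cm[, c]) else 0
        rec <- if (support > 0) cm[c, c] / support else 0
        f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
        total <- total + support
        wsum <- wsum + support * f1
    }
    wsum / total
}

# Adjusted Rand index between two label vectors (used when mclust is not
# exercised); mclust::adjustedRandIndex is preferred where available.
ariOf <- function(a, b) {
    if (requireNamespace("mclust", quietly = TRUE))
        return(mclust::adjustedRandIndex(a, b))
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    sumi <- sum(choose(rowSums(tab), 2))
    sumj <- sum(choose(colSums(tab), 2))
    expected <- sumi * sumj / choose(n, 2)
    (sumij - expected) / ((sumi + sumj) / 2 - expected)
}

# Tiny labelled expression matrix.
toyExpr <- function(values, genes = NULL, samples = NULL) {
    if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
    if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
    dimnames(values) <- list(genes, samples)
    ExpressionMatrix(values)
}

# Build a SubtypeAssignment directly from a label vector (for tests of
# consumers that do not need the clustering step).
toyAssignment <- function(labels) {
    lv <- c("immunity-high", "immunity-medium", "immunity-low")
    new("SubtypeAssignment", assignment = data.frame(
        sample_id = names(labels),
        label = factor(unname(labels), levels = lv),
        cluster_index = as.integer(factor(unname(labels), levels = lv)),
        ordering_key = -as.integer(factor(unname(labels), levels = lv)),
        stringsAsFactors = FALSE))
}

# Clinical table with OS fields only.
toyClinical <- function(ids, time, status) {
    ClinicalTable(data.frame(
        sample_id = ids, survival_time = time, event_status = status,
        grade = NA_character_, idh_status = NA_character_,
        histology = NA_character_, stringsAsFactors = FALSE))
}
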