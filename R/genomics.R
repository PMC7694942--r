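#' @include AllClasses.R accessors.R
NULL

#' Tumor mutation burden per sample
#'
#' TMB is the total count of a sample's somatic mutation records — all
#' variant classes, indels included, by default. Samples listed in
#' `samples` but absent from the table get TMB 0; without a sample list,
#' only samples present in the table are reported.
#'
#' @param muts a [MutationTable-class].
#' @param samples optional character vector enumerating the cohort.
#' @param nonsynonymousOnly count only non-silent variant classes
#'   (excludes `"Silent"`).
#' @param dedupe collapse duplicated identical records before counting
#'   (off by default: duplicates count twice).
#' @return named integer vector of per-sample counts.
#' @export
computeTMB <- function(muts, samples = NULL, nonsynonymousOnly = FALSE,
                       dedupe = FALSE) {
    r <- mutationRecords(muts)
    ids <- if (is.null(samples)) sort(unique(r$sample_id)) else samples
    if (dedupe)
        r <- unique(r[c("sample_id", "gene_symbol", "variant_class",
                        "ref_count", "alt_count")])
    if (nonsynonymousOnly)
        r <- r[r$variant_class != "Silent", , drop = FALSE]
    counts <- table(factor(r$sample_id, levels = ids))
    stats::setNames(as.integer(counts), ids)
}

#' MATH intratumor heterogeneity score
#'
#' MATH (mutant-allele tumor heterogeneity) measures the width of a
#' sample's variant-allele-fraction distribution:
#' `100 * MAD(VAF) / median(VAF)` with the scaled median absolute
#' deviation `MAD = 1.4826 * median(|v - median(v)|)`. Scale-invariant:
#' multiplying all VAFs by a positive constant leaves it unchanged.
#'
#' @param muts a [MutationTable-class].
#' @param sample sample identifier.
#' @param minDepth optional minimum read depth (`ref + alt`) for a variant
#'   to enter the calculation (default 0: every VAF-defined variant is
#'   used).
#' @return the MATH score, or `NA` with a `"reason"` attribute when fewer
#'   than 2 usable VAFs exist or the median VAF is 0.
#' @export
#' @examples
#' mt <- MutationTable(rep("s1", 5), paste0("g", 1:5), rep("Missense", 5),
#'                     ref_count = c(9, 8, 7, 6, 5),
#'                     alt_count = c(1, 2, 3, 4, 5))
#' computeMATH(mt, "s1")  # 49.42
computeMATH <- function(muts, sample, minDepth = 0L) {
    r <- mutationRecords(muts)
    r <- r[r$sample_id == sample & r$vaf_defined &
           (r$ref_count + r$alt_count) >= minDepth, , drop = FALSE]
    v <- r$vaf
    if (length(v) < 2L)
        return(structure(NA_real_, reason = "fewer than 2 usable VAFs"))
    med <- stats::median(v)
    if (med == 0)
        return(structure(NA_real_, reason = "median VAF is 0"))
    100 * stats::mad(v) / med
}

#' Per-sample genomic summary (TMB + MATH)
#'
#' @param muts a [MutationTable-class].
#' @param samples optional cohort sample list (see [computeTMB]).
#' @return data.frame with columns `sample_id`, `tmb`, `math_score`
#'   (`NA` when fewer than 2 usable VAFs) and `n_vaf_used`.
#' @export
genomicSummary <- function(muts, samples = NULL) {
    tmb <- computeTMB(muts, samples = samples)
    r <- mutationRecords(muts)
    math <- vapply(names(tmb),
                   function(s) as.numeric(computeMATH(muts, s)),
                   numeric(1))
    nv <- vapply(names(tmb),
                 function(s) sum(r$sample_id == s & r$vaf_defined),
                 integer(1))
    data.frame(sample_id = names(tmb), tmb = unname(tmb),
               math_score = unname(math), n_vaf_used = unname(nv),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene amplification frequency
#'
#' The amplification frequency of a gene in a sample group is the
#' proportion of samples with a copy-number gain call (threshold call
#' >= +1) for that gene.
#'
#' @param cn a gene-level [CopyNumberTable-class].
#' @param genes gene symbols to report; genes absent from the table return
#'   `NA` with a warning.
#' @param samples optional subset of samples (default: all columns).
#' @return named numeric vector of frequencies in \[0, 1\].
#' @export
amplificationFrequency <- function(cn, genes = NULL, samples = NULL) {
    if (cn@level != "gene")
        stop("amplification frequencies require a gene-level table")
    m <- copyNumberCalls(cn)
    if (is.null(genes)) genes <- rownames(m)
    if (is.null(samples)) samples <- colnames(m)
    absent <- setdiff(genes, rownames(m))
    if (length(absent))
        warning("gene(s) absent from the copy-number table: ",
                paste(absent, collapse = ", "))
    out <- stats::setNames(rep(NA_real_, length(genes)), genes)
    present <- intersect(genes, rownames(m))
    sub <- m[present, samples, drop = FALSE]
    out[present] <- rowMeans(sub >= 1L)
    out
}

#' Cross-product odds ratio with zero-cell correction
#'
#' Computes the cross-product odds ratio of a 2x2 contingency table,
#' applying the Haldane-Anscombe correction (adding 0.5 to every cell)
#' only when at least one cell is zero.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return The odds ratio as a single numeric value.
#' @examples
#' haldaneOR(matrix(c(20, 5, 8, 17), 2))
#' @export
haldaneOR <- function(tab) {
    t2 <- tab
    if (any(tab == 0)) t2 <- tab + 0.5
    (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
}

twoGroupIdx <- function(grouping, groups) {
    lab <- subtypeLabels(grouping)
    g1 <- names(lab)[lab == groups[1L]]
    g2 <- names(lab)[lab == groups[2L]]
    if (!length(g1) || !length(g2))
        stop("empty group: ",
             paste(groups[c(length(g1) == 0L, length(g2) == 0L)],
                   collapse = ", "))
    list(g1 = g1, g2 = g2)
}

#' Compare copy-number alteration frequencies between two subtypes
#'
#' For every feature (chromosome arm or gene), computes per-group
#' amplification (call >= +1), deletion (call <= -1) and total-alteration
#' frequencies, a two-sided Fisher exact p on the total-alteration 2x2
#' table, and BH-adjusted p values across features.
#'
#' @param cn a [CopyNumberTable-class] (arm- or gene-level).
#' @param grouping a [SubtypeAssignment-class].
#' @param groups the two labels to compare (default immunity-high vs
#'   immunity-low).
#' @return data.frame with one row per feature: group-wise amp/del/total
#'   frequencies, their differences (group1 - group2), Fisher `p` and BH
#'   `p_adj`.
#' @export
scnaGroupCompare <- function(cn, grouping,
                             groups = c("immunity-high", "immunity-low")) {
    m <- copyNumberCalls(cn)
    idx <- twoGroupIdx(grouping, groups)
    g1 <- intersect(idx$g1, colnames(m))
    g2 <- intersect(idx$g2, colnames(m))
    if (!length(g1) || !length(g2))
        stop("group with 0 samples in the copy-number table")
    amp1 <- rowMeans(m[, g1, drop = FALSE] >= 1L)
    amp2 <- rowMeans(m[, g2, drop = FALSE] >= 1L)
    del1 <- rowMeans(m[, g1, drop = FALSE] <= -1L)
    del2 <- rowMeans(m[, g2, drop = FALSE] <= -1L)
    alt1 <- rowMeans(m[, g1, drop = FALSE] != 0L)
    alt2 <- rowMeans(m[, g2, drop = FALSE] != 0L)
    p <- vapply(rownames(m), function(f) {
        a <- sum(m[f, g1] != 0L); b <- sum(m[f, g2] != 0L)
        tab <- matrix(c(a, length(g1) - a, b, length(g2) - b), 2L)
        stats::fisher.test(tab)$p.value
    }, numeric(1))
    data.frame(feature = rownames(m),
               amp_freq_1 = unname(amp1), amp_freq_2 = unname(amp2),
               del_freq_1 = unname(del1), del_freq_2 = unname(del2),
               alt_freq_1 = unname(alt1), alt_freq_2 = unname(alt2),
               amp_diff = unname(amp1 - amp2),
               del_diff = unname(del1 - del2),
               alt_diff = unname(alt1 - alt2),
               p = unname(p), p_adj = stats::p.adjust(unname(p), "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare focal copy-number levels between two subtypes
#'
#' For real-valued focal levels (e.g. per-sample mean absolute GISTIC focal
#' amplitude), compares per-sample summaries between two groups with a
#' Mann-Whitney test.
#'
#' @param levels named numeric vector: per-sample focal level summary.
#' @param grouping a [SubtypeAssignment-class].
#' @param groups two labels to compare.
#' @param tail passed to [mannWhitney].
#' @return a `ComparisonResult` list (see [mannWhitney]).
#' @export
focalLevelCompare <- function(levels, grouping,
                              groups = c("immunity-high", "immunity-low"),
                              tail = "two-sided") {
    idx <- twoGroupIdx(grouping, groups)
    mannWhitney(levels[intersect(idx$g1, names(levels))],
                levels[intersect(idx$g2, names(levels))],
                tail = tail, groups = groups)
}

#' Per-gene mutation enrichment screen between two subtypes
#'
#' For every gene mutated in at least `minCount` samples overall, builds
#' the 2x2 mutated/not x group table, computes a two-sided Fisher exact p
#' (on the uncorrected table), a cross-product odds ratio (Haldane 0.5
#' correction only when a cell is zero), BH-adjusted p values across the
#' tested genes, and a pass flag requiring adjusted p < `alpha` AND odds
#' ratio > `orThreshold` — genes passing are enriched in group 1
#' (direction recorded in `direction`).
#'
#' @param muts a [MutationTable-class].
#' @param grouping a [SubtypeAssignment-class].
#' @param groups the two labels to compare.
#' @param minCount minimum number of mutated samples (both groups
#'   combined) for a gene to be tested (default 3).
#' @param alpha adjusted-p threshold for the pass flag.
#' @param orThreshold odds-ratio threshold for the pass flag.
#' @return data.frame, one row per tested gene: mutated/unmutated counts
#'   per group, `odds_ratio`, `p`, `p_adj`, `direction`
#'   (`"group1"`/`"group2"`/`"none"`), and logical `pass`.
#' @export
mutationEnrichmentScreen <- function(muts, grouping,
                                     groups = c("immunity-high",
                                                "immunity-low"),
                                     minCount = 3L, alpha = 0.05,
                                     orThreshold = 2) {
    r <- mutationRecords(muts)
    idx <- twoGroupIdx(grouping, groups)
    n1 <- length(idx$g1); n2 <- length(idx$g2)
    r <- r[r$sample_id %in% c(idx$g1, idx$g2), , drop = FALSE]
    mutated <- unique(r[c("sample_id", "gene_symbol")])
    genes <- sort(unique(mutated$gene_symbol))
    m1 <- vapply(genes, function(g)
        sum(mutated$gene_symbol == g & mutated$sample_id %in% idx$g1), 1L)
    m2 <- vapply(genes, function(g)
        sum(mutated$gene_symbol == g & mutated$sample_id %in% idx$g2), 1L)
    keep <- (m1 + m2) >= minCount
    genes <- genes[keep]; m1 <- m1[keep]; m2 <- m2[keep]
    if (!length(genes))
        return(data.frame(gene = character(), mut_1 = integer(),
                          unmut_1 = integer(), mut_2 = integer(),
                          unmut_2 = integer(), odds_ratio = numeric(),
                          p = numeric(), p_adj = numeric(),
                          direction = character(), pass = logical()))
    res <- lapply(seq_along(genes), function(i) {
        tab <- matrix(c(m1[i], n1 - m1[i], m2[i], n2 - m2[i]), 2L,
                      byrow = TRUE)
        c(p = stats::fisher.test(tab)$p.value, or = haldaneOR(tab))
    })
    p <- vapply(res, `[[`, 0, "p")
    orv <- vapply(res, `[[`, 0, "or")
    padj <- stats::p.adjust(p, "BH")
    pass <- padj < alpha & orv > orThreshold
    direction <- ifelse(m1 / n1 > m2 / n2, "group1",
                        ifelse(m1 / n1 < m2 / n2, "group2", "none"))
    data.frame(gene = genes, mut_1 = m1, unmut_1 = n1 - m1,
               mut_2 = m2, unmut_2 = n2 - m2,
               odds_ratio = orv, p = p, p_adj = padj,
               direction = direction, pass = pass,
               stringsAsFactors = FALSE, row.names = NULL)
}
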