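toyMuts <- function(samples, genes, ref = 10L, alt = 5L) {
    n <- length(samples)
    MutationTable(samples, genes, rep("Missense_Mutation", n),
                  rep(ref, length.out = n), rep(alt, length.out = n))
}

test_that("TMB counts records per sample, honoring sample lists and flags", {
    mt <- toyMuts(c(rep("s1", 5), "s2"), c(paste0("g", 1:5), "g1"))
    expect_equal(computeTMB(mt), c(s1 = 5L, s2 = 1L))
    # enumerated samples absent from the table get zero
    expect_equal(computeTMB(MutationTable(),
                            samples = c("a", "b", "c")),
                 c(a = 0L, b = 0L, c = 0L))
    # duplicated identical record counts twice unless dedupe is set
    dup <- toyMuts(c("s1", "s1"), c("g1", "g1"))
    expect_equal(unname(computeTMB(dup)), 2L)
    expect_equal(unname(computeTMB(dup, dedupe = TRUE)), 1L)
    # invariant to record order and untouched by variant class mix
    mt2 <- MutationTable(c("s2", "s1", "s1", "s1", "s1", "s1"),
                         c("g1", "g5", "g4", "g3", "g2", "g1"),
                         c("Silent", rep("Missense_Mutation", 5)),
                         rep(10L, 6), rep(5L, 6))
    expect_equal(computeTMB(mt2), c(s1 = 5L, s2 = 1L))
    expect_equal(computeTMB(mt2, nonsynonymousOnly = TRUE),
                 c(s1 = 5L, s2 = 0L))
})

test_that("MATH reproduces the closed form and its degenerate cases", {
    mt <- MutationTable(rep("s1", 5), paste0("g", 1:5),
                        rep("Missense_Mutation", 5),
                        ref_count = c(9L, 8L, 7L, 6L, 5L),
                        alt_count = c(1L, 2L, 3L, 4L, 5L))
    # VAFs 0.1..0.5: median 0.3, scaled MAD 0.14826
    expect_equal(as.numeric(computeMATH(mt, "s1")), 49.42, tolerance = 1e-10)

    flat <- MutationTable(rep("s1", 3), paste0("g", 1:3),
                          rep("Missense_Mutation", 3),
                          rep(5L, 3), rep(5L, 3))
    expect_equal(as.numeric(computeMATH(flat, "s1")), 0)

    single <- toyMuts("s1", "g1")
    expect_true(is.na(computeMATH(single, "s1")))
    expect_match(attr(computeMATH(single, "s1"), "reason"), "fewer than 2")
})

test_that("MATH matches the median/MAD oracle and is scale invariant", {
    set.seed(3)
    for (i in 1:200) {
        k <- sample(3:30, 1)
        depth <- 1000L
        vaf <- round(runif(k, 0.05, 0.95), 3)
        alt <- as.integer(round(vaf * depth))
        mt <- MutationTable(rep("s", k), paste0("g", seq_len(k)),
                            rep("Missense_Mutation", k), depth - alt, alt)
        v <- mutationRecords(mt)$vaf
        expect_equal(as.numeric(computeMATH(mt, "s")), mathOracle(v),
                     tolerance = 1e-10)
        # scaling all VAFs by a positive constant leaves MATH unchanged
        expect_equal(mathOracle(v), mathOracle(v * 0.37), tolerance = 1e-10)
    }
})

test_that("amplification frequency is the proportion of gain calls", {
    calls <- matrix(0L, 2, 10,
                    dimnames = list(c("gA", "gB"), paste0("s", 1:10)))
    calls["gA", 1:3] <- c(1L, 2L, 1L)
    cn <- CopyNumberTable(calls, "gene")
    expect_equal(unname(amplificationFrequency(cn, "gA")), 0.3)
    expect_equal(unname(amplificationFrequency(cn, "gB")), 0)
    expect_warning(f <- amplificationFrequency(cn, c("gA", "missing")),
                   "absent")
    expect_true(is.na(f[["missing"]]))
    expect_error(amplificationFrequency(
        CopyNumberTable(calls, "arm"), "gA"), "gene-level")
})

test_that("SCNA group comparison: null case, antisymmetry, planted power", {
    ids <- sprintf("s%02d", 1:40)
    lab <- setNames(rep(c("immunity-high", "immunity-low"), each = 20), ids)
    grp <- toyAssignment(lab)

    # identical groups -> Fisher p = 1 everywhere
    calls <- matrix(rep(c(1L, 0L), 20), 1,
                    dimnames = list("7p", ids))
    same <- scnaGroupCompare(CopyNumberTable(calls, "arm"), grp)
    expect_equal(same$p, 1)

    # swapping the group order negates every frequency difference
    sw <- scnaGroupCompare(CopyNumberTable(calls, "arm"), grp,
                           groups = c("immunity-low", "immunity-high"))
    expect_equal(sw$alt_diff, -same$alt_diff)
    expect_equal(sw$amp_diff, -same$amp_diff)

    # planted gain-rate difference 0.6 vs 0.2 at n = 50/group is detected
    idsL <- sprintf("t%03d", 1:100)
    labL <- setNames(rep(c("immunity-high", "immunity-low"), each = 50),
                     idsL)
    grpL <- toyAssignment(labL)
    hits <- sapply(1:20, function(s) {
        set.seed(s)
        arm <- matrix(ifelse(runif(100) < rep(c(0.6, 0.2), each = 50),
                             1L, 0L), 1, dimnames = list("7p", idsL))
        res <- scnaGroupCompare(CopyNumberTable(arm, "arm"), grpL)
        res$p_adj < 0.05
    })
    expect_gte(mean(hits), 0.9)

    noneLab <- toyAssignment(setNames(rep("immunity-high", 4),
                                      sprintf("s%02d", 1:4)))
    expect_error(scnaGroupCompare(CopyNumberTable(calls, "arm"), noneLab),
                 "empty group")
})

test_that("mutation enrichment screen: odds ratios, thresholds, null case", {
    ids <- c(sprintf("h%02d", 1:10), sprintf("l%02d", 1:10))
    lab <- setNames(rep(c("immunity-high", "immunity-low"), each = 10), ids)
    grp <- toyAssignment(lab)
    # gene mutated in 8/10 of group1, 2/10 of group2 -> cross-product OR 16
    muts <- toyMuts(c(sprintf("h%02d", 1:8), sprintf("l%02d", 1:2)),
                    rep("GENE_X", 10))
    res <- mutationEnrichmentScreen(muts, grp, minCount = 1L)
    expect_equal(res$odds_ratio[res$gene == "GENE_X"], 16)
    expect_equal(res$direction[res$gene == "GENE_X"], "group1")

    # identical mutation patterns in both groups -> nothing passes
    mutsNull <- toyMuts(c(sprintf("h%02d", 1:5), sprintf("l%02d", 1:5)),
                        rep("GENE_Y", 10))
    resNull <- mutationEnrichmentScreen(mutsNull, grp, minCount = 1L)
    expect_false(any(resNull$pass))

    # pass flag exactly reflects adjusted p < 0.05 AND OR > 2
    expect_equal(res$pass, res$p_adj < 0.05 & res$odds_ratio > 2)

    # min_count filter removes sparsely mutated genes
    sparse <- toyMuts("h01", "RARE_GENE")
    resMin <- mutationEnrichmentScreen(sparse, grp, minCount = 3L)
    expect_equal(nrow(resMin), 0L)

    # Haldane correction engages only for zero cells
    mutsZero <- toyMuts(sprintf("h%02d", 1:5), rep("GENE_Z", 5))
    resZ <- mutationEnrichmentScreen(mutsZero, grp, minCount = 1L)
    expect_equal(resZ$odds_ratio, (5.5 * 10.5) / (5.5 * 0.5))
})

test_that("BH adjustment matches the step-up hand computation", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
})
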