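smallSpec <- function(seed = 1L, ...) {
    gliomaCohortSpec(nPerStratum = c(15L, 15L, 15L), nGenes = 500L,
                     seed = seed, ...)
}

test_that("the same seed reproduces a byte-identical cohort on disk", {
    co1 <- generateCohort(smallSpec(seed = 42L))
    co2 <- generateCohort(smallSpec(seed = 42L))
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeCohort(co1, d1)
    writeCohort(co2, d2)
    files <- list.files(d1)
    expect_true(length(files) >= 8L)
    for (f in files)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))

    co3 <- generateCohort(smallSpec(seed = 43L))
    expect_false(identical(exprValues(co1@expression),
                           exprValues(co3@expression)))
})

test_that("cohort files round-trip through the package readers", {
    co <- generateCohort(smallSpec(seed = 5L))
    d <- withr::local_tempdir()
    writeCohort(co, d)
    em <- readExpression(file.path(d, "expression.tsv"))
    expect_equal(exprValues(em), exprValues(co@expression),
                 tolerance = 1e-10)
    gs <- readGMT(file.path(d, "immune_sets.gmt"))
    expect_equal(geneSets(gs), geneSets(co@immuneSets))
    mt <- readMAF(file.path(d, "mutations.maf"))
    expect_equal(nrow(mutationRecords(mt)),
                 nrow(mutationRecords(co@mutations)))
    cn <- readCopyNumber(file.path(d, "copynumber_arms.tsv"), "arm")
    expect_equal(copyNumberCalls(cn), copyNumberCalls(co@armCalls))
})

test_that("generator marginals match the spec parameters within 3 standard errors", {
    sp <- gliomaCohortSpec(nPerStratum = c(170L, 165L, 165L),
                           nGenes = 500L, seed = 99L)
    co <- generateCohort(sp)
    truth <- groundTruth(co)
    ids <- names(truth)

    # Poisson mutation-count means per stratum
    tmb <- computeTMB(co@mutations, samples = ids)
    for (i in 1:3) {
        s <- c("high", "medium", "low")[i]
        obs <- tmb[truth == s]
        se <- sd(obs) / sqrt(length(obs))
        expect_lt(abs(mean(obs) - sp@tmbMean[i]), 3 * se)
    }

    # Beta VAF means per stratum (binomial read noise is mean-preserving)
    r <- mutationRecords(co@mutations)
    for (i in 1:3) {
        s <- c("high", "medium", "low")[i]
        v <- r$vaf[r$sample_id %in% ids[truth == s] & r$vaf_defined]
        se <- sd(v) / sqrt(length(v))
        expect_lt(abs(mean(v) - sp@vafMean[i]), 3 * se)
    }

    # Bernoulli rates: grade IV, IDH-mutant, arm gains
    cd <- clinicalData(co@clinical)
    arm <- copyNumberCalls(co@armCalls)
    for (i in 1:3) {
        s <- c("high", "medium", "low")[i]
        sel <- cd$sample_id %in% ids[truth == s]
        p <- mean(cd$grade[sel] == "IV")
        expect_lt(abs(p - sp@gradeIVProb[i]),
                  3 * sqrt(sp@gradeIVProb[i] * (1 - sp@gradeIVProb[i]) /
                           sum(sel)))
        q <- mean(cd$idh_status[sel] == "mutant")
        expect_lt(abs(q - sp@idhMutantProb[i]),
                  3 * sqrt(sp@idhMutantProb[i] * (1 - sp@idhMutantProb[i]) /
                           sum(sel)))
        g <- mean(arm[, ids[truth == s]] == 1L)
        nObs <- nrow(arm) * sum(truth == s)
        expect_lt(abs(g - sp@armGainProb[i]),
                  3 * sqrt(sp@armGainProb[i] * (1 - sp@armGainProb[i]) /
                           nObs))
    }
})

test_that("planted shifts separate strata in enrichment space; the null does not", {
    # shifted cohort: high-stratum mean ssGSEA exceeds low-stratum mean
    seps <- sapply(1:5, function(s) {
        co <- generateCohort(smallSpec(seed = 100L + s,
                                       delta = c(3, 1.5, 0)))
        es <- scores(ssgseaScores(co@expression, co@immuneSets,
                                  normalize = FALSE))
        truth <- groundTruth(co)[colnames(es)]
        mean(es[, truth == "high"]) > mean(es[, truth == "low"])
    })
    expect_true(all(seps))

    # delta = 0 everywhere: clustering cannot recover the strata
    aris <- sapply(1:5, function(s) {
        co <- generateCohort(smallSpec(seed = 200L + s,
                                       delta = c(0, 0, 0)))
        res <- subtypeCohort(co@expression, co@immuneSets)
        truth <- groundTruth(co)
        ariOf(subtypeLabels(res$subtypes)[names(truth)], truth)
    })
    expect_lt(mean(abs(aris)), 0.1)
})

test_that("cohort invariants: cross-references resolve and IDH ties to its mutation record", {
    co <- generateCohort(smallSpec(seed = 77L))
    ids <- sampleIDs(co@expression)
    expect_setequal(clinicalData(co@clinical)$sample_id, ids)
    expect_setequal(names(groundTruth(co)), ids)
    expect_setequal(colnames(copyNumberCalls(co@armCalls)), ids)
    expect_true(all(mutationRecords(co@mutations)$sample_id %in% ids))

    cd <- clinicalData(co@clinical)
    mutIDH <- unique(mutationRecords(co@mutations)$sample_id[
        mutationRecords(co@mutations)$gene_symbol == "IDH1"])
    expect_setequal(mutIDH, cd$sample_id[cd$idh_status == "mutant"])

    expect_error(generateCohort(gliomaCohortSpec(nGenes = 100L)),
                 "exceeds nGenes")
})
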