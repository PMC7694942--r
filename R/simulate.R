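#' @include AllClasses.R accessors.R io.R
NULL

#' The 28 immune cell types of the subtyping panel
#'
#' Names of the immune-cell signatures used for clustering and
#' classification.
#'
#' @format character vector of length 28.
#' @export
immuneCellTypes <- c(
    "Activated B cell", "Activated CD4 T cell", "Activated CD8 T cell",
    "Activated dendritic cell", "CD56bright natural killer cell",
    "CD56dim natural killer cell", "Central memory CD4 T cell",
    "Central memory CD8 T cell", "Effector memory CD4 T cell",
    "Effector memory CD8 T cell", "Eosinophil", "Gamma delta T cell",
    "Immature B cell", "Immature dendritic cell", "Macrophage",
    "Mast cell", "MDSC", "Memory B cell", "Monocyte",
    "Natural killer cell", "Natural killer T cell", "Neutrophil",
    "Plasmacytoid dendritic cell", "Regulatory T cell",
    "T follicular helper cell", "Type 1 T helper cell",
    "Type 17 T helper cell", "Type 2 T helper cell")

#' Synthetic-cohort generator specification
#'
#' Builds a [CohortSpec-class] describing a three-stratum glioma-like
#' cohort. The defaults plant every qualitative ordering the subtyping
#' study design expects: immune-set expression shifted high > medium > low
#' (adjacent strata separated by 1.5 noise sds), mutation burden highest in
#' the high-immunity stratum, VAF dispersion (hence MATH) lowest there,
#' copy-number gains most frequent there, survival worst there (largest
#' hazard), grade IV most and IDH-mutant least frequent there.
#'
#' @param nGenes,nPerStratum,nImmuneSets,setSize,setOverlap cohort layout;
#'   see [CohortSpec-class].
#' @param delta,noiseSD,promotingBoost,inhibitingBoost expression model.
#' @param tmbMean,vafMean,vafConcentration mutation model.
#' @param armGainProb,armLossProb,nArms,geneGainProb copy-number model.
#' @param hazard,censorFraction survival model (hazard per month).
#' @param gradeIVProb,idhMutantProb clinical label model.
#' @param enrichedGeneProb,nEnrichedGenes,nBackgroundGenes mutation-screen
#'   planting.
#' @param seed RNG seed.
#' @return A validated [CohortSpec-class].
#' @export
gliomaCohortSpec <- function(nGenes = 1500L,
                             nPerStratum = c(60L, 60L, 60L),
                             nImmuneSets = 28L, setSize = 10L,
                             setOverlap = 0,
                             delta = c(3, 1.5, 0), noiseSD = 1,
                             promotingBoost = 1.15,
                             inhibitingBoost = 0.85,
                             tmbMean = c(70, 60, 52),
                             vafMean = c(0.35, 0.35, 0.35),
                             vafConcentration = c(30, 19, 13),
                             armGainProb = c(0.40, 0.25, 0.15),
                             armLossProb = c(0.30, 0.20, 0.10),
                             nArms = 10L,
                             geneGainProb = c(0.50, 0.30, 0.15),
                             hazard = c(0.040, 0.035, 0.015),
                             censorFraction = 0.3,
                             gradeIVProb = c(0.60, 0.40, 0.14),
                             idhMutantProb = c(0.20, 0.50, 0.80),
                             enrichedGeneProb = c(0.50, 0.25, 0.08),
                             nEnrichedGenes = 5L,
                             nBackgroundGenes = 150L,
                             seed = 1L) {
    new("CohortSpec", nGenes = as.integer(nGenes),
        nPerStratum = as.integer(nPerStratum),
        nImmuneSets = as.integer(nImmuneSets),
        setSize = as.integer(setSize), setOverlap = setOverlap,
        delta = delta, noiseSD = noiseSD,
        promotingBoost = promotingBoost,
        inhibitingBoost = inhibitingBoost,
        tmbMean = tmbMean, vafMean = vafMean,
        vafConcentration = vafConcentration,
        armGainProb = armGainProb, armLossProb = armLossProb,
        nArms = as.integer(nArms), geneGainProb = geneGainProb,
        hazard = hazard, censorFraction = censorFraction,
        gradeIVProb = gradeIVProb, idhMutantProb = idhMutantProb,
        enrichedGeneProb = enrichedGeneProb,
        nEnrichedGenes = as.integer(nEnrichedGenes),
        nBackgroundGenes = as.integer(nBackgroundGenes),
        seed = as.integer(seed))
}

## Cytokine / cytokine-receptor panel carried by the gene-level
## copy-number table.
cytokinePanel <- c("IL2", "IL6", "IL10", "CXCL9", "CXCL10", "CCL2", "CCL5",
                   "TNF", "IFNG", "IL1B", "CSF1R", "IL7R", "CXCR4", "CCR5",
                   "IL4R", "TGFB1", "IL12A", "IL15", "CX3CL1", "TNFRSF9")

## Planted screen-enrichment genes (mutated more often in the high
## stratum) and the low-stratum-enriched gene.
enrichedGeneNames <- c("EGFR", "PTEN", "NF1", "RB1", "MUC16")
lowEnrichedGene <- "IDH1"

#' Generate a synthetic cohort with planted immune structure
#'
#' Draws a full cohort — expression, immune gene sets, auxiliary
#' signatures, mutations, gene- and arm-level copy number, clinical table —
#' from a [CohortSpec-class]. All randomness flows from `spec@seed`; the
#' same spec always yields an identical cohort.
#'
#' Expression is baseline log-scale noise (`5 + Normal(0, noiseSD)`) with
#' the stratum shift `delta` added to every immune-set gene (boosted /
#' damped for the immune-promoting / immune-inhibiting marker sets, scaled
#' by 0.3 for the stromal signature). Mutation counts are Poisson with the
#' stratum mean (planted screen genes and the IDH-like gene contribute on
#' top of a background pool); VAFs arise from Beta-distributed true allele
#' fractions observed through binomial read sampling at Poisson(100) depth.
#'
#' @param spec a [CohortSpec-class].
#' @return A [SyntheticCohort-class].
#' @export
generateCohort <- function(spec) {
    validObject(spec)
    withSeed(spec@seed, {
        nS <- spec@nPerStratum
        n <- sum(nS)
        stratum <- rep(c("high", "medium", "low"), nS)
        ids <- sprintf("S%03d", seq_len(n))
        genes <- sprintf("GENE%05d", seq_len(spec@nGenes))

        ## ---- gene-set layout -------------------------------------------
        nImm <- spec@nImmuneSets * spec@setSize
        pool <- sample(genes)
        immGenes <- pool[seq_len(nImm)]
        immuneSets <- split(immGenes,
                            rep(seq_len(spec@nImmuneSets),
                                each = spec@setSize))
        if (spec@setOverlap > 0) {
            nShare <- round(spec@setOverlap * spec@setSize)
            shared <- immGenes[seq_len(max(nShare, 1L))]
            immuneSets <- lapply(immuneSets, function(g)
                unique(c(g[seq_len(spec@setSize - nShare)],
                         shared[seq_len(nShare)])))
        }
        nm <- immuneCellTypes[seq_len(min(28L, spec@nImmuneSets))]
        if (spec@nImmuneSets > 28L)
            nm <- c(nm, sprintf("Immune set %d", 29:spec@nImmuneSets))
        names(immuneSets) <- nm
        used <- nImm
        take <- function(k) {
            g <- pool[used + seq_len(k)]; used <<- used + k; g
        }
        stromalGenes <- take(2L * spec@setSize)
        cd8Markers <- take(spec@setSize)
        tregMarkers <- take(spec@setSize)
        m1Markers <- take(spec@setSize)
        m2Markers <- take(spec@setSize)
        pdl1Gene <- take(1L)
        immuneSignature <- sample(immGenes, min(40L, length(immGenes)))
        signatures <- GeneSetList(list(
            immune_signature = immuneSignature,
            stromal_signature = stromalGenes,
            CD8_markers = cd8Markers,
            Treg_markers = tregMarkers,
            M1_markers = m1Markers,
            M2_markers = m2Markers,
            PDL1 = pdl1Gene))

        ## ---- expression ------------------------------------------------
        ds <- stats::setNames(spec@delta, c("high", "medium", "low"))
        shift <- ds[stratum] * spec@noiseSD
        v <- matrix(stats::rnorm(spec@nGenes * n, mean = 5,
                                 sd = spec@noiseSD),
                    spec@nGenes, n, dimnames = list(genes, ids))
        addShift <- function(gs, mult = 1) {
            v[gs, ] <<- v[gs, , drop = FALSE] +
                rep(shift * mult, each = length(gs))
        }
        addShift(setdiff(immGenes, c(cd8Markers, tregMarkers)))
        addShift(cd8Markers, spec@promotingBoost)
        addShift(m1Markers, spec@promotingBoost)
        addShift(tregMarkers, spec@inhibitingBoost)
        addShift(m2Markers, spec@inhibitingBoost)
        addShift(stromalGenes, 0.3)
        addShift(pdl1Gene, 1)
        expr <- ExpressionMatrix(v, logScale = TRUE)

        ## ---- clinical (drawn before mutations so IDH status can drive
        ##      the IDH-like mutation record) ----------------------------
        par3 <- function(x) stats::setNames(x, c("high", "medium", "low"))
        hz <- par3(spec@hazard)[stratum]
        evtTime <- stats::rexp(n, rate = hz)
        censored <- stats::runif(n) < spec@censorFraction
        time <- ifelse(censored, stats::runif(n, 0, evtTime), evtTime)
        status <- as.integer(!censored)
        gradeIV <- stats::runif(n) < par3(spec@gradeIVProb)[stratum]
        grade <- ifelse(gradeIV, "IV",
                        ifelse(stats::runif(n) < 0.5, "II", "III"))
        idhMut <- stats::runif(n) < par3(spec@idhMutantProb)[stratum]
        clinical <- ClinicalTable(data.frame(
            sample_id = ids,
            survival_time = round(time, 3),
            event_status = status,
            grade = grade,
            idh_status = ifelse(idhMut, "mutant", "wildtype"),
            histology = ifelse(gradeIV, "GBM", "LGG"),
            stringsAsFactors = FALSE), timeUnit = "months")

        ## ---- mutations -------------------------------------------------
        variantClasses <- c("Missense_Mutation", "Nonsense_Mutation",
                            "Silent", "Frame_Shift_Del", "Splice_Site")
        classProb <- c(0.55, 0.1, 0.2, 0.1, 0.05)
        bgGenes <- sprintf("MGENE%03d", seq_len(spec@nBackgroundGenes))
        enrGenes <- enrichedGeneNames[
            seq_len(min(spec@nEnrichedGenes, length(enrichedGeneNames)))]
        if (spec@nEnrichedGenes > length(enrichedGeneNames))
            enrGenes <- c(enrGenes,
                          sprintf("ENRGENE%02d",
                                  seq_len(spec@nEnrichedGenes -
                                          length(enrichedGeneNames))))
        enrP <- par3(spec@enrichedGeneProb)
        tmbM <- par3(spec@tmbMean)
        vafA <- par3(spec@vafMean * spec@vafConcentration)
        vafB <- par3((1 - spec@vafMean) * spec@vafConcentration)
        recs <- vector("list", n)
        for (i in seq_len(n)) {
            s <- stratum[i]
            planted <- enrGenes[stats::runif(length(enrGenes)) < enrP[[s]]]
            if (idhMut[i]) planted <- c(planted, lowEnrichedGene)
            expectedPlanted <- length(enrGenes) * enrP[[s]] +
                par3(spec@idhMutantProb)[[s]]
            bgMean <- max(tmbM[[s]] - expectedPlanted, 0)
            nBg <- stats::rpois(1L, bgMean)
            gs <- c(planted, sample(bgGenes, nBg, replace = TRUE))
            k <- length(gs)
            if (k == 0L) next
            depth <- stats::rpois(k, 100) + 10L
            vafTrue <- stats::rbeta(k, vafA[[s]], vafB[[s]])
            alt <- stats::rbinom(k, depth, vafTrue)
            recs[[i]] <- data.frame(
                sample_id = ids[i], gene_symbol = gs,
                variant_class = sample(variantClasses, k, replace = TRUE,
                                       prob = classProb),
                ref_count = depth - alt, alt_count = alt,
                stringsAsFactors = FALSE)
        }
        recs <- do.call(rbind, recs)
        mutations <- MutationTable(recs$sample_id, recs$gene_symbol,
                                   recs$variant_class, recs$ref_count,
                                   recs$alt_count)

        ## ---- copy number -----------------------------------------------
        gGain <- par3(spec@geneGainProb)[stratum]
        geneCalls <- matrix(0L, length(cytokinePanel), n,
                            dimnames = list(cytokinePanel, ids))
        for (i in seq_len(n)) {
            gain <- stats::runif(length(cytokinePanel)) < gGain[i]
            loss <- !gain & stats::runif(length(cytokinePanel)) < 0.05
            geneCalls[gain, i] <- ifelse(
                stats::runif(sum(gain)) < 0.7, 1L, 2L)
            geneCalls[loss, i] <- ifelse(
                stats::runif(sum(loss)) < 0.7, -1L, -2L)
        }
        armNames <- c("1p", "1q", "7p", "7q", "9p", "10p", "10q", "13q",
                      "19q", "22q")[seq_len(min(spec@nArms, 10L))]
        if (spec@nArms > 10L)
            armNames <- c(armNames,
                          sprintf("arm%02d", seq_len(spec@nArms - 10L)))
        aGain <- par3(spec@armGainProb)[stratum]
        aLoss <- par3(spec@armLossProb)[stratum]
        armCalls <- matrix(0L, length(armNames), n,
                           dimnames = list(armNames, ids))
        for (i in seq_len(n)) {
            gain <- stats::runif(length(armNames)) < aGain[i]
            loss <- !gain & stats::runif(length(armNames)) < aLoss[i]
            armCalls[gain, i] <- 1L
            armCalls[loss, i] <- -1L
        }

        new("SyntheticCohort",
            expression = expr,
            immuneSets = GeneSetList(immuneSets),
            signatures = signatures,
            mutations = mutations,
            copyNumber = CopyNumberTable(geneCalls, "gene"),
            armCalls = CopyNumberTable(armCalls, "arm"),
            clinical = clinical,
            truth = stats::setNames(stratum, ids),
            spec = spec)
    })
}

#' Write a synthetic cohort as the pipeline's on-disk formats
#'
#' Emits exactly the files the readers consume: `expression.tsv`,
#' `immune_sets.gmt`, `signatures.gmt`, `mutations.maf`,
#' `copynumber_genes.tsv`, `copynumber_arms.tsv`, `clinical.tsv`, plus
#' `truth.tsv` (planted strata, analysis code should not read it) and a
#' JSON spec record. Output is byte-identical for identical specs.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(dir, f)
    writeExpression(cohort@expression, fp("expression.tsv"))
    writeGMT(cohort@immuneSets, fp("immune_sets.gmt"))
    writeGMT(cohort@signatures, fp("signatures.gmt"))
    writeMAF(cohort@mutations, fp("mutations.maf"))
    writeCopyNumber(cohort@copyNumber, fp("copynumber_genes.tsv"))
    writeCopyNumber(cohort@armCalls, fp("copynumber_arms.tsv"))
    writeClinical(cohort@clinical, fp("clinical.tsv"))
    utils::write.table(
        data.frame(sample_id = names(cohort@truth),
                   stratum = unname(cohort@truth)),
        fp("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    sp <- cohort@spec
    slots <- slotNames(sp)
    meta <- lapply(stats::setNames(slots, slots), function(s) slot(sp, s))
    jsonlite::write_json(meta, fp("cohort_spec.json"), auto_unbox = FALSE,
                         pretty = TRUE, digits = NA)
    invisible(dir)
}

#' Synthetic immune/stromal demonstration signatures
#'
#' Loads the small synthetic immune and stromal marker signatures shipped
#' with the package (`estimate_signatures_synthetic.gmt`). These are
#' hand-picked canonical marker genes for demonstration on matrices that
#' use human gene symbols; they are NOT the published immune/stromal
#' signature gene lists, which users should supply for real cohorts.
#'
#' @return list with `immune` and `stromal` [GeneSetList-class] objects.
#' @export
syntheticEstimateSignatures <- function() {
    gmt <- readGMT(system.file("extdata",
                               "estimate_signatures_synthetic.gmt",
                               package = "immunotype", mustWork = TRUE))
    sets <- geneSets(gmt)
    list(immune = GeneSetList(sets["immune_signature_synthetic"]),
         stromal = GeneSetList(sets["stromal_signature_synthetic"]))
}
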