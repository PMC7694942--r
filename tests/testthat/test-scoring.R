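test_that("ssGSEA reproduces the hand-computed running sum", {
    em <- toyExpr(matrix(c(4, 3, 2, 1, 4, 3, 2, 1), ncol = 2))
    sets <- GeneSetList(list(S1 = c("g1", "g2")))
    es <- scores(ssgseaScores(em, sets, alpha = 0.25, normalize = FALSE))
    # weights 4^0.25 and 3^0.25; step differences 0.5180, 1, 0.5, 0
    expect_equal(unname(es["S1", 1]), 2.0180, tolerance = 1e-4)
    # identical expression vectors give identical scores
    expect_equal(es[, 1], es[, 2])
})

test_that("ssGSEA matches the step-by-step oracle on random instances", {
    set.seed(42)
    for (i in 1:100) {
        nG <- sample(4:10, 1)
        x <- round(rnorm(nG), 2)  # rounding makes occasional ties
        genes <- paste0("g", seq_len(nG))
        names(x) <- genes
        k <- sample(seq_len(nG - 1L), 1)
        setGenes <- sample(genes, k)
        alpha <- sample(c(0, 0.25, 1), 1)
        em <- toyExpr(cbind(x, x + rnorm(nG)), genes = genes)
        es <- scores(ssgseaScores(em, GeneSetList(list(S = setGenes)),
                                  alpha = alpha, normalize = FALSE))
        expect_equal(unname(es["S", 1]), ssgseaOracle(x, setGenes, alpha),
                     tolerance = 1e-9)
    }
})

test_that("ssGSEA with alpha = 0 equals the unweighted Kolmogorov sum", {
    x <- setNames(c(8, 7, 6, 5, 4, 3, 2, 1), paste0("g", 1:8))
    setGenes <- paste0("g", 1:4)  # top half
    em <- toyExpr(cbind(x, rev(x)), genes = names(x))
    es <- scores(ssgseaScores(em, GeneSetList(list(S = setGenes)),
                              alpha = 0, normalize = FALSE))
    # unweighted: each in-set step adds 1/4 to P_in
    pin <- cumsum(c(1, 1, 1, 1, 0, 0, 0, 0)) / 4
    pout <- cumsum(c(0, 0, 0, 0, 1, 1, 1, 1)) / 4
    expect_equal(unname(es["S", 1]), sum(pin - pout), tolerance = 1e-12)
})

test_that("ssGSEA is invariant to strictly monotone transforms", {
    set.seed(7)
    x <- rnorm(20)
    em1 <- toyExpr(cbind(x, x))
    em2 <- toyExpr(cbind(exp(x), exp(x)))  # strictly monotone transform
    sets <- GeneSetList(list(S = paste0("g", 1:6), T = paste0("g", 10:15)))
    e1 <- scores(ssgseaScores(em1, sets, normalize = FALSE))
    e2 <- scores(ssgseaScores(em2, sets, normalize = FALSE))
    expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("range normalization maps scores to [0,1]; degenerate sets are handled", {
    set.seed(1)
    em <- toyExpr(matrix(rnorm(60), 10))
    sets <- GeneSetList(list(A = paste0("g", 1:3), B = paste0("g", 5:9)))
    es <- scores(ssgseaScores(em, sets, normalize = TRUE))
    expect_true(all(es >= 0 & es <= 1))

    expect_warning(
        esNA <- ssgseaScores(em, GeneSetList(list(Z = c("nope1", "nope2"))),
                             normalize = FALSE),
        "no gene overlap")
    expect_true(all(is.na(scores(esNA))))
    expect_error(
        ssgseaScores(em, GeneSetList(list(All = paste0("g", 1:10)))),
        "ALL genes")
})

test_that("immune/stromal scores are additive and purity follows the cosine law", {
    # closed form at estimate_score = 0
    expect_equal(cos(0.6049872018), 0.8225094, tolerance = 1e-7)

    set.seed(11)
    base <- matrix(rnorm(200 * 12, mean = 5), 200, 12,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
    immuneGenes <- paste0("g", 1:20)
    stromalGenes <- paste0("g", 21:40)
    # sample 1 strictly higher on every immune-signature gene
    base[immuneGenes, 1] <- base[immuneGenes, 2] + 2
    base[setdiff(rownames(base), immuneGenes), 1] <-
        base[setdiff(rownames(base), immuneGenes), 2]
    em <- ExpressionMatrix(base)
    est <- estimateScores(em, GeneSetList(list(i = immuneGenes)),
                          GeneSetList(list(s = stromalGenes)))
    expect_equal(est$estimate_score, est$immune_score + est$stromal_score)
    expect_gt(est$immune_score[1], est$immune_score[2])
    # purity strictly decreasing in the combined score over all pairs
    ord <- order(est$estimate_score)
    expect_true(all(diff(est$purity_raw[ord]) < 0))
    expect_true(all(est$purity >= 0 & est$purity <= 1))
})

test_that("signature ratios are log2 quotients of linear-scale means", {
    v <- matrix(log2(c(8, 8, 2, 2, 4, 4, 4, 4)), 4,
                dimnames = list(paste0("g", 1:4), c("s1", "s2")))
    em <- ExpressionMatrix(v, logScale = TRUE)
    r <- signatureRatio(em, c("g1", "g2"), c("g3", "g4"))
    expect_equal(r$ratio[1], 2)       # log2(8/2)
    expect_equal(r$ratio[2], 0)       # equal means

    same <- signatureRatio(em, c("g1", "g2"), c("g1", "g2"))
    expect_equal(same$ratio, c(0, 0))

    swapped <- signatureRatio(em, c("g3", "g4"), c("g1", "g2"))
    expect_equal(swapped$ratio, -r$ratio)

    lin <- ExpressionMatrix(matrix(c(-1, 3, 2, 2), 2,
                                   dimnames = list(c("a", "b"),
                                                   c("s1", "s2"))),
                            logScale = FALSE)
    expect_error(signatureRatio(lin, "a", "b"), "linear-scale")
})
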