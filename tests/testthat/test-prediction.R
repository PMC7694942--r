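test_that("weighted F-score matches the hand case and the confusion oracle", {
    cm <- matrix(c(2L, 0L, 1L, 1L), 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
    m <- confusionMetrics(cm)
    expect_equal(m$accuracy, 0.75)
    expect_equal(m$weightedF, 0.7333, tolerance = 1e-4)  # F1 = 0.8 and 2/3

    set.seed(100)
    for (i in 1:100) {
        k <- sample(2:4, 1)
        cm <- matrix(rpois(k * k, 3), k,
                     dimnames = list(LETTERS[1:k], LETTERS[1:k]))
        if (sum(cm) == 0) cm[1, 1] <- 1
        expect_equal(confusionMetrics(cm)$weightedF, weightedFOracle(cm),
                     tolerance = 1e-12)
    }
})

makeSeparable <- function(n = 30L, seed = 1L, delta = 4) {
    set.seed(seed)
    cls <- rep(c("immunity-high", "immunity-medium", "immunity-low"),
               length.out = n)
    shift <- c(`immunity-high` = delta, `immunity-medium` = 0,
               `immunity-low` = -delta)[cls]
    v <- sapply(shift, function(s) pmin(pmax(rnorm(28, s / 2, 0.5), -3), 3))
    dimnames(v) <- list(paste0("f", 1:28), sprintf("s%02d", seq_len(n)))
    list(features = new("NormalizedFeatureMatrix", values = v,
                        droppedFeatures = character()),
         labels = toyAssignment(setNames(cls, colnames(v))))
}

test_that("a separable cohort is fit perfectly and deterministically", {
    d <- makeSeparable(seed = 2)
    fit <- trainSubtypeClassifier(d$features, d$labels, seed = 7)
    rep1 <- crossCohortPredict(fit, d$features, d$labels)
    expect_equal(rep1@accuracy, 1.0)
    # resubstitution accuracy at least matches out-of-bag accuracy
    oob <- 1 - fit$model$err.rate[fit$nTrees, "OOB"]
    expect_gte(rep1@accuracy, oob)

    fit2 <- trainSubtypeClassifier(d$features, d$labels, seed = 7)
    expect_identical(fit$importance, fit2$importance)

    labs <- subtypeLabels(d$labels)
    labs[] <- "immunity-high"
    expect_error(trainSubtypeClassifier(d$features, toyAssignment(labs)),
                 "single class")
})

test_that("prediction validates features and handles single-sample test sets", {
    d <- makeSeparable(seed = 3)
    fit <- trainSubtypeClassifier(d$features, d$labels, seed = 1)
    short <- new("NormalizedFeatureMatrix",
                 values = featureValues(d$features)[1:20, , drop = FALSE],
                 droppedFeatures = character())
    expect_error(crossCohortPredict(fit, short, d$labels), "f21")

    one <- new("NormalizedFeatureMatrix",
               values = featureValues(d$features)[, 1, drop = FALSE],
               droppedFeatures = character())
    oneLab <- toyAssignment(subtypeLabels(d$labels)[1])
    rep1 <- crossCohortPredict(fit, one, oneLab)
    expect_equal(sum(rep1@confusion), 1L)
    expect_false(anyNA(rep1@perClass$f1))
})

test_that("null features with shuffled labels give chance-level CV accuracy", {
    accs <- sapply(1:20, function(s) {
        set.seed(1000 + s)
        v <- matrix(pmin(pmax(rnorm(28 * 60), -3), 3), 28, 60,
                    dimnames = list(paste0("f", 1:28), sprintf("s%02d", 1:60)))
        cls <- sample(rep(c("immunity-high", "immunity-medium",
                            "immunity-low"), each = 20))
        d <- list(features = new("NormalizedFeatureMatrix", values = v,
                                 droppedFeatures = character()),
                  labels = toyAssignment(setNames(cls, colnames(v))))
        kfoldCV(d$features, d$labels, k = 10, nTrees = 200,
                seed = s)@accuracy
    })
    se <- sqrt((1 / 3) * (2 / 3) / (20 * 60))
    expect_lt(abs(mean(accs) - 1 / 3), 3 * se)
})

test_that("cross-validation is stratified, deterministic, and supports leave-one-out", {
    d <- makeSeparable(n = 40L, seed = 4)
    r1 <- kfoldCV(d$features, d$labels, k = 10, nTrees = 100, seed = 5)
    r2 <- kfoldCV(d$features, d$labels, k = 10, nTrees = 100, seed = 5)
    expect_identical(r1@confusion, r2@confusion)
    expect_gte(r1@accuracy, 0.9)

    d12 <- makeSeparable(n = 12L, seed = 6)
    expect_warning(loo <- kfoldCV(d12$features, d12$labels, k = 12,
                                  nTrees = 50, seed = 1),
                   "fewer than k")
    expect_equal(sum(loo@confusion), 12L)
})

test_that("planted-signal features occupy the top importance ranks", {
    hits <- sapply(1:20, function(s) {
        set.seed(2000 + s)
        n <- 90L
        cls <- rep(c("immunity-high", "immunity-medium", "immunity-low"),
                   each = 30)
        v <- matrix(rnorm(28 * n), 28, n,
                    dimnames = list(paste0("f", 1:28), sprintf("s%02d", 1:n)))
        signal <- paste0("f", 1:5)
        shift <- c(`immunity-high` = 1.5, `immunity-medium` = 0,
                   `immunity-low` = -1.5)[cls]
        v[signal, ] <- v[signal, ] + rep(shift, each = 5)
        v <- pmin(pmax(v, -3), 3)
        d <- list(features = new("NormalizedFeatureMatrix", values = v,
                                 droppedFeatures = character()),
                  labels = toyAssignment(setNames(cls, colnames(v))))
        fit <- trainSubtypeClassifier(d$features, d$labels, seed = s)
        top5 <- names(sort(fit$importance, decreasing = TRUE))[1:5]
        setequal(top5, signal)
    })
    expect_gte(mean(hits), 0.9)
})
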