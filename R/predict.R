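#' @include AllClasses.R accessors.R subtype.R
NULL

#' Classification metrics from a confusion matrix
#'
#' Computes overall accuracy, per-class precision/recall/F1 with supports,
#' and the support-weighted mean F1 (the weighted F-score) from a square
#' confusion matrix with true classes in rows and predicted classes in
#' columns. A class with zero precision + recall gets F1 = 0.
#'
#' @param confusion square numeric matrix, rows = true, columns =
#'   predicted, identical dimnames.
#' @return list with elements `accuracy`, `weightedF` and `perClass`
#'   (data.frame: class, precision, recall, f1, support).
#' @export
#' @examples
#' cm <- matrix(c(2, 1, 0, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' confusionMetrics(cm)
confusionMetrics <- function(confusion) {
    stopifnot(nrow(confusion) == ncol(confusion),
              identical(rownames(confusion), colnames(confusion)))
    tp <- diag(confusion)
    support <- rowSums(confusion)
    predicted <- colSums(confusion)
    precision <- ifelse(predicted > 0, tp / predicted, 0)
    recall <- ifelse(support > 0, tp / support, 0)
    f1 <- ifelse(precision + recall > 0,
                 2 * precision * recall / (precision + recall), 0)
    list(accuracy = sum(tp) / sum(confusion),
         weightedF = sum(support * f1) / sum(support),
         perClass = data.frame(class = rownames(confusion),
                               precision = unname(precision),
                               recall = unname(recall),
                               f1 = unname(f1),
                               support = unname(support),
                               stringsAsFactors = FALSE, row.names = NULL))
}

makeReport <- function(confusion, importance = numeric(),
                       trainCohort = NA_character_, seed = NA_integer_) {
    m <- confusionMetrics(confusion)
    storage.mode(confusion) <- "integer"
    new("ClassifierReport", accuracy = m$accuracy, weightedF = m$weightedF,
        perClass = m$perClass, confusion = confusion,
        importance = importance, trainCohort = trainCohort,
        seed = as.integer(seed))
}

alignedLabels <- function(features, labels) {
    v <- featureValues(features)
    lab <- subtypeLabels(labels)
    missing <- setdiff(colnames(v), names(lab))
    if (length(missing))
        stop("samples without subtype labels: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    factor(lab[colnames(v)], levels = levels(labels@assignment$label))
}

#' Train a Random Forest subtype classifier
#'
#' Fits a Random Forest (500 trees by default, all immune-cell features,
#' conventional defaults for feature subsampling and depth) on per-cohort
#' Z-clipped enrichment features against the cohort's clustering-derived
#' subtype labels. Deterministic for a given seed.
#'
#' @param features a [NormalizedFeatureMatrix-class] (features x samples).
#' @param labels a [SubtypeAssignment-class] covering the same samples.
#' @param nTrees number of trees.
#' @param seed RNG seed for the forest.
#' @param cohort optional training-cohort identifier carried into reports.
#' @return A classifier handle (class `"subtypeClassifier"`) holding the
#'   fitted forest, the feature names, and the training metadata; feature
#'   importances (mean decrease in node impurity) via `$importance`.
#' @export
trainSubtypeClassifier <- function(features, labels, nTrees = 500L, seed = 1L,
                                   cohort = "train") {
    v <- featureValues(features)
    y <- alignedLabels(features, labels)
    if (nlevels(droplevels(y)) < 2L)
        stop("training set contains a single class")
    fit <- withSeed(seed,
        randomForest::randomForest(x = t(v), y = droplevels(y),
                                   ntree = nTrees, importance = FALSE))
    imp <- stats::setNames(as.numeric(fit$importance[, "MeanDecreaseGini"]),
                           rownames(fit$importance))
    structure(list(model = fit, featureNames = rownames(v),
                   classLevels = levels(y), importance = imp,
                   nTrees = nTrees, seed = as.integer(seed),
                   cohort = cohort),
              class = "subtypeClassifier")
}

#' @export
print.subtypeClassifier <- function(x, ...) {
    cat(sprintf("subtypeClassifier: %d trees on %d features (cohort %s)\n",
                x$nTrees, length(x$featureNames), x$cohort))
    invisible(x)
}

#' Predict subtypes in an independent cohort
#'
#' Applies a trained classifier to a test cohort's own per-cohort normalized
#' features and scores the predictions against the test cohort's
#' clustering-derived labels (the evaluation contract: the clustering
#' defines truth in each cohort).
#'
#' @param model a classifier handle from [trainSubtypeClassifier].
#' @param testFeatures a [NormalizedFeatureMatrix-class], normalized within
#'   the test cohort.
#' @param testLabels the test cohort's [SubtypeAssignment-class].
#' @return A [ClassifierReport-class].
#' @export
crossCohortPredict <- function(model, testFeatures, testLabels) {
    v <- featureValues(testFeatures)
    missing <- setdiff(model$featureNames, rownames(v))
    if (length(missing))
        stop("test cohort lacks model feature(s): ",
             paste(missing, collapse = ", "))
    y <- alignedLabels(testFeatures, testLabels)
    pred <- stats::predict(model$model,
                           t(v[model$featureNames, , drop = FALSE]))
    pred <- factor(as.character(pred), levels = levels(y))
    cm <- table(true = y, predicted = pred)
    cm <- unclass(cm)
    names(dimnames(cm)) <- NULL
    makeReport(cm, importance = model$importance,
               trainCohort = model$cohort, seed = model$seed)
}

#' Stratified k-fold cross-validation
#'
#' Splits samples into `k` class-stratified folds, trains on each k-1
#' complement and pools the out-of-fold predictions into a single report
#' (micro pooling: the metrics are computed once over all held-out
#' predictions). Classes with fewer than `k` members are spread as evenly
#' as possible, with a warning.
#'
#' @param features a [NormalizedFeatureMatrix-class].
#' @param labels a [SubtypeAssignment-class].
#' @param k number of folds (`k = n` gives leave-one-out).
#' @param nTrees trees per forest.
#' @param seed RNG seed governing fold assignment and every fold's forest.
#' @param cohort cohort identifier for the report.
#' @return A [ClassifierReport-class] over the pooled out-of-fold
#'   predictions.
#' @export
kfoldCV <- function(features, labels, k = 10L, nTrees = 500L, seed = 1L,
                    cohort = "train") {
    v <- featureValues(features)
    y <- alignedLabels(features, labels)
    n <- ncol(v)
    if (n < k)
        stop("need n >= k samples")
    if (any(table(droplevels(y)) < k))
        warning("class(es) with fewer than k members; ",
                "folds stratified as evenly as possible")
    withSeed(seed, {
        fold <- integer(n)
        for (cl in levels(droplevels(y))) {
            idx <- sample(which(y == cl))
            fold[idx] <- rep_len(seq_len(k), length(idx))
        }
        pred <- factor(rep(NA_character_, n), levels = levels(y))
        for (f in seq_len(k)) {
            test <- fold == f
            if (!any(test)) next
            fit <- randomForest::randomForest(
                x = t(v[, !test, drop = FALSE]),
                y = droplevels(y[!test]), ntree = nTrees)
            p <- stats::predict(fit, t(v[, test, drop = FALSE]))
            pred[test] <- as.character(p)
        }
        cm <- unclass(table(true = y, predicted = pred))
        names(dimnames(cm)) <- NULL
        makeReport(cm, trainCohort = cohort, seed = seed)
    })
}
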