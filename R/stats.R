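#' @include AllClasses.R accessors.R
NULL

comparisonResult <- function(test, groups, statistic, p, tail, method,
                             direction, n) {
    structure(list(test = test, groups = groups, statistic = statistic,
                   p = p, tail = tail, method = method,
                   direction = direction, n = n),
              class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
    cat(sprintf("%s (%s, %s): statistic = %.4g, p = %.4g [n = %s]\n",
                x$test, x$tail, x$method, x$statistic, x$p,
                paste(x$n, collapse = "/")))
    invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. With `tail = "one-sided-greater"` the
#' alternative is that the first group is stochastically greater (the
#' a-priori subtype ordering high > medium > low). The p value comes from
#' exact enumeration when the combined n is at most 12 and there are no
#' ties, and from the normal approximation with tie correction and
#' continuity correction otherwise; `method` forces either path.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param tail `"two-sided"` or `"one-sided-greater"` (x greater).
#' @param method `"auto"`, `"exact"` or `"approximate"`.
#' @param groups labels for the two groups (reporting only).
#' @return A `ComparisonResult` list: test, groups, statistic (U for the
#'   first group), p, tail, method used, effect direction, group sizes.
#' @export
mannWhitney <- function(x, y, tail = c("two-sided", "one-sided-greater"),
                        method = c("auto", "exact", "approximate"),
                        groups = c("x", "y")) {
    tail <- match.arg(tail)
    method <- match.arg(method)
    stopifnot(length(x) >= 1L, length(y) >= 1L)
    ties <- anyDuplicated(c(x, y)) > 0L
    useExact <- switch(method,
        auto = (length(x) + length(y) <= 12L) && !ties,
        exact = TRUE,
        approximate = FALSE)
    alt <- if (tail == "two-sided") "two.sided" else "greater"
    wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = alt, exact = useExact,
                           correct = TRUE))
    comparisonResult("Mann-Whitney U", groups,
                     statistic = unname(wt$statistic), p = wt$p.value,
                     tail = tail,
                     method = if (useExact) "exact" else "normal-approx",
                     direction = if (stats::median(x) >= stats::median(y))
                                     groups[1L] else groups[2L],
                     n = c(length(x), length(y)))
}

#' One-way ANOVA
#'
#' Classic F test across two or more groups. The degenerate all-constant
#' case (zero between- and within-group variance) is reported as F = 0,
#' p = 1; zero within-group variance with distinct means gives F = Inf,
#' p = 0.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n > number of
#'   groups).
#' @param labels optional group labels.
#' @return A `ComparisonResult` list with the F statistic.
#' @export
anovaOneway <- function(groups, labels = NULL) {
    k <- length(groups)
    stopifnot(k >= 2L)
    n <- lengths(groups)
    if (sum(n) <= k)
        stop("total n must exceed the number of groups")
    if (is.null(labels)) labels <- paste0("group", seq_len(k))
    vals <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(labels, n), levels = labels)
    grand <- mean(vals)
    ssb <- sum(n * (vapply(groups, mean, 0) - grand)^2)
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
    if (ssw == 0) {
        if (ssb == 0)
            return(comparisonResult("one-way ANOVA", labels, 0, 1,
                                    "two-sided", "F", "none", n))
        return(comparisonResult("one-way ANOVA", labels, Inf, 0,
                                "two-sided", "F",
                                labels[which.max(vapply(groups, mean, 0))],
                                n))
    }
    f <- (ssb / (k - 1)) / (ssw / (sum(n) - k))
    p <- stats::pf(f, k - 1, sum(n) - k, lower.tail = FALSE)
    comparisonResult("one-way ANOVA", labels, f, p, "two-sided", "F",
                     labels[which.max(vapply(groups, mean, 0))], n)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p value from the
#' asymptotic t approximation.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return A `ComparisonResult` list with `statistic` = rho, or rho = NA
#'   with a reason in `method` when either vector is constant.
#' @export
spearmanCor <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        return(comparisonResult("Spearman correlation", c("x", "y"),
                                NA_real_, NA_real_, "two-sided",
                                "undefined: constant vector", "none",
                                length(x)))
    ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
    comparisonResult("Spearman correlation", c("x", "y"),
                     statistic = unname(ct$estimate), p = ct$p.value,
                     tail = "two-sided", method = "t-approx",
                     direction = if (ct$estimate >= 0) "positive"
                                 else "negative",
                     n = length(x))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1, input
#' order preserved, never smaller than the raw p.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values in input order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Kaplan-Meier curves and log-rank tests between subtypes
#'
#' Product-limit survival curves per group plus every pairwise two-group
#' log-rank chi-square (1 df) and the k-group log-rank. Samples with
#' missing time/status or group are excluded; a group left with no
#' observations is dropped with a warning; pairs with no events are
#' reported as not computable (`NA`).
#'
#' @param clinical a [ClinicalTable-class]. For `endpoint = "DFS"` the
#'   table must additionally carry `dfs_time` and `dfs_status` columns.
#' @param grouping a [SubtypeAssignment-class], or a named character/factor
#'   vector of group labels per sample.
#' @param endpoint `"OS"` (default, `survival_time`/`event_status`) or
#'   `"DFS"`.
#' @return list of class `"SurvivalComparison"`: `curves` (data.frame
#'   group/time/surv/n_risk), `pairwise` (data.frame with chisq and p per
#'   pair), `overall` (k-group chisq, df, p), `endpoint`, `timeUnit`.
#' @export
kmLogrank <- function(clinical, grouping, endpoint = c("OS", "DFS")) {
    endpoint <- match.arg(endpoint)
    d <- clinicalData(clinical)
    if (endpoint == "DFS") {
        if (!all(c("dfs_time", "dfs_status") %in% names(d)))
            stop("DFS endpoint requires dfs_time and dfs_status columns")
        time <- d$dfs_time; status <- d$dfs_status
    } else {
        time <- d$survival_time; status <- d$event_status
    }
    grp <- if (is(grouping, "SubtypeAssignment")) subtypeLabels(grouping)
           else stats::setNames(as.character(grouping), names(grouping))
    g <- grp[d$sample_id]
    keep <- !is.na(time) & !is.na(status) & !is.na(g)
    if (any(!keep))
        warning(sum(!keep), " sample(s) excluded for missing data")
    df <- data.frame(time = time[keep], status = status[keep],
                     group = g[keep])
    present <- sort(unique(df$group))
    if (length(present) < 2L)
        stop("need >= 2 non-empty groups")
    fit <- survival::survfit(survival::Surv(time, status) ~ group,
                             data = df)
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    curves <- data.frame(group = strata, time = fit$time,
                         surv = fit$surv, n_risk = fit$n.risk,
                         stringsAsFactors = FALSE, row.names = NULL)
    pairs <- utils::combn(present, 2L, simplify = FALSE)
    pw <- do.call(rbind, lapply(pairs, function(pr) {
        sub <- df[df$group %in% pr, ]
        if (sum(sub$status) == 0)
            return(data.frame(group1 = pr[1L], group2 = pr[2L],
                              chisq = NA_real_, p = NA_real_,
                              n = nrow(sub),
                              note = "no events: not computable"))
        sd2 <- survival::survdiff(survival::Surv(time, status) ~ group,
                                  data = sub)
        data.frame(group1 = pr[1L], group2 = pr[2L],
                   chisq = unname(sd2$chisq),
                   p = stats::pchisq(sd2$chisq, 1L, lower.tail = FALSE),
                   n = nrow(sub), note = "")
    }))
    overall <- if (sum(df$status) == 0) {
        list(chisq = NA_real_, df = length(present) - 1L, p = NA_real_,
             note = "no events: not computable")
    } else {
        sdk <- survival::survdiff(survival::Surv(time, status) ~ group,
                                  data = df)
        list(chisq = unname(sdk$chisq), df = length(present) - 1L,
             p = stats::pchisq(sdk$chisq, length(present) - 1L,
                               lower.tail = FALSE),
             note = "")
    }
    structure(list(curves = curves, pairwise = pw, overall = overall,
                   endpoint = endpoint, timeUnit = clinical@timeUnit),
              class = "SurvivalComparison")
}

#' @export
print.SurvivalComparison <- function(x, ...) {
    cat(sprintf("Survival comparison (%s, time in %s)\n", x$endpoint,
                x$timeUnit))
    cat(sprintf("  overall log-rank: chisq = %.3g (df %d), p = %.3g\n",
                x$overall$chisq, x$overall$df, x$overall$p))
    for (i in seq_len(nrow(x$pairwise)))
        cat(sprintf("  %s vs %s: chisq = %.3g, p = %.3g\n",
                    x$pairwise$group1[i], x$pairwise$group2[i],
                    x$pairwise$chisq[i], x$pairwise$p[i]))
    invisible(x)
}
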