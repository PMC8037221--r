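#' @include AllClasses.R
NULL

#' Wilcoxon rank-sum comparison of responder vs non-responder scores
#'
#' Two-sided rank-sum test: exact when the combined sample is small
#' (n1 + n2 <= 20) and tie-free, otherwise the normal approximation with
#' continuity and tie correction. The reported p-value is floored at 1e-5
#' (values below are uniformly set to exactly 1e-5); the raw value is
#' retained.
#'
#' @param scores_r,scores_nr numeric score vectors for responders and
#'   non-responders; both non-empty.
#' @return list with \code{p_raw}, \code{p_reported}, \code{direction}
#'   (sign of the responder-minus-non-responder median difference) and
#'   the group sizes.
#' @export
wilcoxonResponseTest <- function(scores_r, scores_nr) {
    if (!length(scores_r) || !length(scores_nr))
        stop("both groups must be non-empty")
    n <- length(scores_r) + length(scores_nr)
    ties <- anyDuplicated(c(scores_r, scores_nr)) > 0L
    p <- suppressWarnings(stats::wilcox.test(
        scores_r, scores_nr, alternative = "two.sided",
        exact = (n <= 20L && !ties), correct = TRUE))$p.value
    list(p_raw = p, p_reported = max(p, 1e-5),
         direction = sign(stats::median(scores_r) -
                          stats::median(scores_nr)),
         n_responders = length(scores_r),
         n_non_responders = length(scores_nr))
}

#' Univariate logistic association of a score with response
#'
#' Fits label ~ score with the score standardized to unit SD, so the odds
#' ratio is per score-SD. Complete separation is flagged and returned with
#' an infinite-OR sentinel rather than crashing.
#'
#' @param score numeric vector.
#' @param labels binary vector (1 = responder) or logical.
#' @return list with \code{or}, \code{ci} (Wald 95\%), \code{p},
#'   \code{coef}, \code{separation}.
#' @export
logisticAssociation <- function(score, labels) {
    y <- as.integer(labels)
    if (length(unique(y[!is.na(y)])) < 2L)
        stop("both classes must be present")
    if (stats::sd(score) == 0)
        stop("score is constant; logistic fit undefined")
    z <- (score - mean(score)) / stats::sd(score)
    fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
    b <- stats::coef(fit)[["z"]]
    se <- sqrt(stats::vcov(fit)["z", "z"])
    sep <- !fit$converged || abs(b) > 15 ||
        all(abs(fit$fitted.values - y) < 1e-8)
    if (sep)
        return(list(or = if (b > 0) Inf else 0, ci = c(NA_real_, NA_real_),
                    p = NA_real_, coef = b, separation = TRUE))
    pval <- 2 * stats::pnorm(-abs(b / se))
    list(or = exp(b), ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
         p = pval, coef = b, separation = FALSE)
}

#' Empirical ROC curve and AUC
#'
#' AUC by the Mann-Whitney identity: (concordant pairs + half ties) /
#' (n1 * n0), computed on direction-oriented scores (direction -1 negates
#' the score first, so negatively correlated biomarkers are read in their
#' documented direction).
#'
#' @param score numeric vector.
#' @param labels binary (1 = responder) or logical vector.
#' @param direction +1 or -1.
#' @return list with \code{auc} and \code{roc} (data.frame of the
#'   empirical step curve: fpr, tpr).
#' @export
rocAuc <- function(score, labels, direction = 1L) {
    y <- as.integer(labels)
    n1 <- sum(y == 1L)
    n0 <- sum(y == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present")
    s <- if (direction == -1L) -score else score
    r <- rank(s, ties.method = "average")
    auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- sort(unique(s), decreasing = TRUE)
    roc <- data.frame(
        fpr = c(0, vapply(thr, function(t) sum(s >= t & y == 0L) / n0,
                          numeric(1))),
        tpr = c(0, vapply(thr, function(t) sum(s >= t & y == 1L) / n1,
                          numeric(1))))
    list(auc = auc, roc = roc)
}

#' Sample-size-weighted prediction score
#'
#' Aggregates one biomarker's per-dataset AUCs into a single score
#' weighted by dataset size: \eqn{\sum_i Size_i AUC_i / \sum_i Size_i}.
#' Datasets flagged as the biomarker's training data are excluded before
#' aggregation.
#'
#' @param auc numeric vector of per-dataset AUCs.
#' @param size positive numeric vector of dataset sample sizes.
#' @param excluded_as_training logical vector; \code{TRUE} entries are
#'   dropped.
#' @return the weighted mean AUC.
#' @examples
#' predictionScore(c(0.6, 0.8), c(10, 30))  # 0.75
#' @export
predictionScore <- function(auc, size,
                            excluded_as_training = rep(FALSE, length(auc))) {
    stopifnot(length(auc) == length(size))
    keep <- !excluded_as_training
    auc <- auc[keep]; size <- size[keep]
    if (!length(auc))
        stop("no dataset left after training-set exclusion")
    if (any(size <= 0))
        stop("dataset sizes must be positive")
    sum(size * auc) / sum(size)
}

#' Median split with the smaller-group tie rule
#'
#' Samples strictly above the median go to \code{"high"}, strictly below
#' to \code{"low"}; samples exactly at the median join whichever strict
#' group is smaller (ties in strict-group size broken toward
#' \code{"low"}).
#'
#' @param scores numeric vector, n >= 2, not all equal.
#' @return character vector of \code{"high"}/\code{"low"} assignments.
#' @examples
#' medianSplit(c(1, 2, 2, 3, 4))  # low low low high high
#' @export
medianSplit <- function(scores) {
    if (length(scores) < 2L)
        stop("median split needs at least two samples")
    m <- stats::median(scores)
    g <- ifelse(scores > m, "high", ifelse(scores < m, "low", NA))
    if (all(is.na(g)))
        stop("all scores equal; no split possible")
    at_median <- is.na(g)
    n_high <- sum(g == "high", na.rm = TRUE)
    n_low <- sum(g == "low", na.rm = TRUE)
    g[at_median] <- if (n_high < n_low) "high" else "low"
    stats::setNames(g, names(scores))
}

#' Sensitivity and specificity at the median threshold
#'
#' Predicted-positive is the \code{"high"} group of
#' \code{\link{medianSplit}} applied to direction-oriented scores.
#'
#' @inheritParams rocAuc
#' @return list with \code{sensitivity}, \code{specificity} and the
#'   2 x 2 confusion \code{table}.
#' @export
sensitivitySpecificityAtMedian <- function(score, labels, direction = 1L) {
    y <- as.integer(labels)
    if (!any(y == 1L) || !any(y == 0L))
        stop("both classes must be present")
    s <- if (direction == -1L) -score else score
    grp <- medianSplit(s)
    tp <- sum(grp == "high" & y == 1L)
    fn <- sum(grp == "low" & y == 1L)
    tn <- sum(grp == "low" & y == 0L)
    fp <- sum(grp == "high" & y == 0L)
    list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         table = matrix(c(tp, fp, fn, tn), 2L,
                        dimnames = list(predicted = c("high", "low"),
                                        truth = c("responder",
                                                  "non_responder"))))
}

#' Fisher's exact association of median-split score with objective response
#'
#' Builds the 2 x 2 table of median-split score group against objective
#' response and tests it with the two-sided Fisher exact test
#' (point-probability rule). Datasets with 20 or fewer evaluable patients
#' are ineligible and are returned unmodelled.
#'
#' @param score numeric vector.
#' @param objective_response binary vector (1 = CR/PR).
#' @param min_n minimum eligible sample count (default 21, i.e. "more
#'   than 20 patients").
#' @return list with \code{eligible}, and when eligible \code{p} and the
#'   2 x 2 \code{table}; degenerate margins give p = 1 with a warning.
#' @export
fisherOrrAssociation <- function(score, objective_response, min_n = 21L) {
    y <- as.integer(objective_response)
    n <- length(y)
    if (n < min_n)
        return(list(eligible = FALSE, n = n))
    grp <- medianSplit(score)
    tab <- table(factor(grp, levels = c("high", "low")),
                 factor(y, levels = c(1L, 0L)))
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
        warning("degenerate margin in the 2x2 table; p set to 1")
        return(list(eligible = TRUE, p = 1, table = tab, n = n))
    }
    list(eligible = TRUE, p = stats::fisher.test(tab)$p.value,
         table = tab, n = n)
}

#' Spearman correlation and average-linkage clustering of biomarker scores
#'
#' Pairwise Spearman rank correlation over shared non-missing samples,
#' followed by average-linkage hierarchical clustering on the distance
#' 1 - rho. Constant biomarker rows have undefined correlations and are
#' excluded with a warning.
#'
#' @param scores a \linkS4class{BiomarkerScores} or a biomarker x sample
#'   numeric matrix; >= 2 biomarkers and >= 3 samples.
#' @return list with \code{rho} (correlation matrix), \code{hclust} and
#'   \code{order} (leaf order of biomarker ids).
#' @export
biomarkerCorrelationClustering <- function(scores) {
    m <- if (methods::is(scores, "BiomarkerScores")) scoreMatrix(scores)
         else scores
    m <- m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
    const <- apply(m, 1L, function(r) stats::sd(r, na.rm = TRUE) == 0)
    if (any(const)) {
        warning("excluding constant biomarker row(s): ",
                paste(rownames(m)[const], collapse = ", "))
        m <- m[!const, , drop = FALSE]
    }
    if (nrow(m) < 2L || ncol(m) < 3L)
        stop("need at least two biomarkers and three samples")
    rho <- stats::cor(t(m), method = "spearman",
                      use = "pairwise.complete.obs")
    hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
    list(rho = rho, hclust = hc, order = rownames(rho)[hc$order])
}
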