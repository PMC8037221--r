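#' @include AllClasses.R
NULL

#' Enrichment parameters
#'
#' @param alpha rank-weight exponent for the hit increments (>= 0).
#' @param normalize divide the ssGSEA enrichment score by N - |set|?
#' @param coverage_threshold minimum measured gene fraction for a
#'   signature to be evaluable (see \code{\link{validateSignatureCoverage}}).
#' @return list of parameters consumed by the scoring engine.
#' @export
enrichmentParams <- function(alpha = 0.25, normalize = FALSE,
                             coverage_threshold = 1.0) {
    stopifnot(alpha >= 0, coverage_threshold >= 0, coverage_threshold <= 1)
    list(alpha = alpha, normalize = normalize,
         coverage_threshold = coverage_threshold)
}

## One sample's rank-weighted random walk. `rho` are the rank values of the
## genes (highest expression = N), `ord` the walk order (descending
## expression), `hit` marks set membership in the same gene order as rho.
.enrichWalk <- function(rho, ord, hit, alpha) {
    n <- length(rho)
    m <- sum(hit)
    steps <- numeric(n)
    w <- rho[ord]^alpha
    hit_ord <- hit[ord]
    steps[hit_ord] <- w[hit_ord] / sum(w[hit_ord])
    steps[!hit_ord] <- -1 / (n - m)
    cumsum(steps)
}

#' Per-sample ssGSEA enrichment scores
#'
#' For each sample, genes are ranked by expression (descending; ties take
#' average ranks) and a rank-weighted random walk steps down the ordered
#' list: in-set genes add \code{rank^alpha} normalized over the set, out-of-
#' set genes subtract \code{1/(N - |set|)}. The enrichment score is the sum
#' of the walk (integral form); with \code{normalize = TRUE} it is divided
#' by \code{N - |set|}. Rank-based, so any strictly increasing per-sample
#' transform of the expression values leaves the scores unchanged.
#'
#' @param expr numeric matrix, genes x samples.
#' @param gene_set character vector of set genes; genes absent from
#'   \code{expr} are ignored (coverage gating happens upstream).
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide the score by N - |set|?
#' @return numeric vector of per-sample enrichment scores.
#' @export
ssgseaScores <- function(expr, gene_set, alpha = 0.25, normalize = FALSE) {
    hit <- rownames(expr) %in% gene_set
    m <- sum(hit)
    if (m == 0L)
        stop("no gene of the set is present in the expression matrix")
    if (m >= nrow(expr))
        stop("gene set must be a strict subset of the gene universe")
    es <- vapply(seq_len(ncol(expr)), function(s) {
        x <- expr[, s]
        rho <- rank(x, ties.method = "average")
        ord <- order(-x)
        sum(.enrichWalk(rho, ord, hit, alpha))
    }, numeric(1))
    if (normalize) es <- es / (nrow(expr) - m)
    names(es) <- colnames(expr)
    es
}

#' Per-sample GSVA-style enrichment scores
#'
#' Each gene's expression is first transformed to a relative-expression
#' statistic across samples: the Gaussian-kernel cumulative density
#' \eqn{z_{gs} = n^{-1} \sum_j \Phi((x_{gs} - x_{gj}) / h_g)} with
#' Silverman's rule bandwidth per gene. Per sample, genes are ranked by
#' that statistic and the set is scored by the rank-weighted random walk,
#' taking the maximum deviation from zero (signed) as the enrichment score.
#' Location shifts of a gene across all samples cancel in the kernel CDF,
#' so scores are invariant to them.
#'
#' @param expr numeric matrix, genes x samples, >= 2 samples.
#' @param gene_sets named list of gene vectors.
#' @param alpha rank-weight exponent (default 0.25).
#' @return matrix, sets x samples, of enrichment scores.
#' @export
gsvaScores <- function(expr, gene_sets, alpha = 0.25) {
    if (ncol(expr) < 2L)
        stop("GSVA-style scoring needs at least two samples ",
             "(the across-sample density is undefined otherwise)")
    z <- .kernelCdf(expr)
    out <- matrix(NA_real_, length(gene_sets), ncol(expr),
                  dimnames = list(names(gene_sets), colnames(expr)))
    for (k in seq_along(gene_sets)) {
        hit <- rownames(expr) %in% gene_sets[[k]]
        if (sum(hit) == 0L)
            stop("no gene of set '", names(gene_sets)[k], "' is present")
        if (sum(hit) >= nrow(expr))
            stop("gene set must be a strict subset of the gene universe")
        out[k, ] <- vapply(seq_len(ncol(z)), function(s) {
            zs <- z[, s]
            rho <- rank(zs, ties.method = "average")
            walk <- .enrichWalk(rho, order(-zs), hit, alpha)
            walk[which.max(abs(walk))]
        }, numeric(1))
    }
    out
}

## Gaussian-kernel CDF across samples, Silverman's rule bandwidth per gene.
.kernelCdf <- function(expr) {
    n <- ncol(expr)
    out <- t(vapply(seq_len(nrow(expr)), function(g) {
        x <- expr[g, ]
        h <- 0.9 * min(stats::sd(x), stats::IQR(x) / 1.34) * n^(-1 / 5)
        if (!is.finite(h) || h <= 0) h <- 1e-8
        vapply(x, function(xi) mean(stats::pnorm((xi - x) / h)), numeric(1))
    }, numeric(n), USE.NAMES = FALSE))
    dimnames(out) <- dimnames(expr)
    out
}
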