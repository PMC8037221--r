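#' @include AllClasses.R signatures.R enrichment.R
NULL

#' Biomarker score families
#'
#' One function per scoring method. All operate on a genes x samples
#' log2(TPM+1) matrix and return a per-sample numeric vector (or matrix for
#' multi-population scorers); \code{\link{scoreAll}} dispatches a whole
#' registry at once with coverage gating.
#'
#' @param expr numeric matrix, genes x samples, log2(TPM+1).
#' @param gene single gene symbol.
#' @param genes character vector of member genes.
#' @param weights named numeric per-gene weights.
#' @param pairs two-column character matrix of ordered gene pairs.
#' @param sig a \linkS4class{SignatureDefinition}.
#' @param params list from \code{\link{enrichmentParams}}.
#' @name scoreFamilies
NULL

#' @rdname scoreFamilies
#' @export
scoreSingleGene <- function(expr, gene) {
    if (!gene %in% rownames(expr))
        stop("gene '", gene, "' not measured")
    expr[gene, ]
}

#' @rdname scoreFamilies
#' @export
scoreMeanSignature <- function(expr, genes) {
    colMeans(expr[genes, , drop = FALSE])
}

#' @rdname scoreFamilies
#' @export
scoreWeightedSum <- function(expr, weights) {
    g <- names(weights)
    if (is.null(g) || !all(g %in% rownames(expr)))
        stop("weights must be named by measured genes")
    stats::setNames(as.vector(t(expr[g, , drop = FALSE]) %*% weights),
                    colnames(expr))
}

#' @rdname scoreFamilies
#' @details \code{scoreImpres} counts, per sample, the ordered gene pairs
#'   whose first member is strictly more expressed than the second; ties
#'   contribute 0. The score is an integer in [0, n_pairs].
#' @export
scoreImpres <- function(expr, pairs) {
    miss <- setdiff(as.vector(pairs), rownames(expr))
    if (length(miss))
        stop("pair gene(s) not measured: ", paste(miss, collapse = ", "))
    a <- expr[pairs[, 1L], , drop = FALSE]
    b <- expr[pairs[, 2L], , drop = FALSE]
    colSums(a > b)
}

#' @rdname scoreFamilies
#' @param gene_set character vector for a single enrichment set.
#' @export
scoreSsgsea <- function(expr, gene_set, params = enrichmentParams()) {
    ssgseaScores(expr, gene_set, alpha = params$alpha,
                 normalize = params$normalize)
}

#' @rdname scoreFamilies
#' @param subset_sets named list of gene sets (e.g. the nine T-cell
#'   subsets); each is ssGSEA-scored, z-scored across samples (population
#'   SD) and the z-scores averaged over subsets.
#' @export
scoreTis <- function(expr, subset_sets, params = enrichmentParams()) {
    if (ncol(expr) < 2L)
        stop("subset z-scoring needs at least two samples")
    es <- t(vapply(subset_sets, function(gs)
        ssgseaScores(expr, gs, alpha = params$alpha,
                     normalize = params$normalize),
        numeric(ncol(expr))))
    colMeans(zScoreGenes(es))
}

#' @rdname scoreFamilies
#' @param gene_sets named list of gene sets for the GSVA-style collection;
#'   the final score is the mean over the collection's sets.
#' @export
scoreGsvaMean <- function(expr, gene_sets, params = enrichmentParams()) {
    colMeans(gsvaScores(expr, gene_sets, alpha = params$alpha))
}

#' @rdname scoreFamilies
#' @details \code{scorePc1} takes the first principal component of the
#'   z-scored member-gene submatrix (samples as observations), with the
#'   sign oriented so the score correlates positively with the members'
#'   mean expression.
#' @export
scorePc1 <- function(expr, genes) {
    if (ncol(expr) < 3L)
        stop("PC1 scoring needs at least three samples")
    sub <- expr[genes, , drop = FALSE]
    z <- zScoreGenes(sub)
    keep <- !rownames(z) %in% attr(z, "flagged")
    if (sum(keep) < 2L)
        stop("PC1 scoring needs at least two member genes with variance")
    z <- z[keep, , drop = FALSE]
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
    s <- pc$x[, 1L]
    anchor <- colMeans(sub)
    if (stats::sd(anchor) > 0 && stats::cor(s, anchor) < 0) s <- -s
    stats::setNames(s, colnames(expr))
}

#' @rdname scoreFamilies
#' @param up,down character vectors of the up- and down-program genes.
#' @details \code{scoreUpDown} centers each gene across samples and then
#'   takes the per-sample mean over the up genes minus the mean over the
#'   down genes.
#' @export
scoreUpDown <- function(expr, up, down) {
    if (!length(up) || !length(down))
        stop("up/down scoring needs non-empty up and down gene lists")
    sub <- expr[unique(c(up, down)), , drop = FALSE]
    centered <- sub - rowMeans(sub)
    colMeans(centered[up, , drop = FALSE]) -
        colMeans(centered[down, , drop = FALSE])
}

#' @rdname scoreFamilies
#' @details \code{scoreIps} z-scores each member gene across samples,
#'   averages z within each weighted component, averages component scores
#'   within the four categories (MHC, EC, SC, CP), averages the category
#'   scores and maps the aggregate affinely onto [0, 10] with clamping
#'   (0 at or below \code{zero_at}, 10 at or above \code{ten_at}).
#' @export
scoreIps <- function(expr, sig, params = enrichmentParams()) {
    comp_w <- unlist(sig@extra$component_weights)
    comp_cat <- unlist(sig@extra$component_category)
    if (is.null(comp_w) || is.null(comp_cat) ||
        !setequal(names(sig@geneSets), names(comp_w)))
        stop("IPS scheme needs component_weights/component_category ",
             "aligned with its gene sets")
    if (!setequal(unique(comp_cat), c("MHC", "EC", "SC", "CP")))
        stop("IPS scheme must cover the four categories MHC/EC/SC/CP")
    zero_at <- sig@extra$map$zero_at %||% 0
    ten_at <- sig@extra$map$ten_at %||% 3
    z <- zScoreGenes(expr[requiredGenes(sig), , drop = FALSE])
    comp <- t(vapply(names(sig@geneSets), function(cn)
        comp_w[[cn]] * colMeans(z[sig@geneSets[[cn]], , drop = FALSE]),
        numeric(ncol(expr))))
    cat_scores <- t(vapply(c("MHC", "EC", "SC", "CP"), function(ct)
        colMeans(comp[comp_cat[rownames(comp)] == ct, , drop = FALSE]),
        numeric(ncol(expr))))
    agg <- colMeans(cat_scores)
    10 * pmin(pmax((agg - zero_at) / (ten_at - zero_at), 0), 1)
}

#' @rdname scoreFamilies
#' @param markers character vector of one population's marker genes; the
#'   abundance estimate is their arithmetic mean on the log2 scale.
#' @export
scoreMcp <- function(expr, markers) {
    colMeans(expr[markers, , drop = FALSE])
}

## dispatch one signature; assumes coverage already passed
.scoreOne <- function(sig, expr, ext, params) {
    switch(sig@method,
        single_gene = scoreSingleGene(expr, sig@genes[1L]),
        mean = scoreMeanSignature(expr, sig@genes),
        weighted_sum = scoreWeightedSum(expr, sig@weights),
        pairwise = scoreImpres(expr, sig@pairs),
        ssgsea = if (length(sig@geneSets) > 1L)
                     scoreTis(expr, sig@geneSets, params)
                 else
                     scoreSsgsea(expr, sig@geneSets[[1L]], params),
        gsva_mean = scoreGsvaMean(expr, sig@geneSets, params),
        pc1 = scorePc1(expr, sig@genes),
        up_down = scoreUpDown(expr, sig@geneSets$up, sig@geneSets$down),
        ips_scheme = scoreIps(expr, sig, params),
        mcp = scoreMcp(expr, sig@genes),
        external = {
            col <- sig@extra$column %||% sig@id
            if (!is.null(ext) && col %in% colnames(ext))
                stats::setNames(as.numeric(ext[[col]]), colnames(expr))
            else rep(NA_real_, ncol(expr))
        },
        stop("no scorer for method '", sig@method, "'"))
}

#' Score every registry biomarker on a cohort
#'
#' Applies the coverage rule (a biomarker whose genes are not all measured
#' is not evaluated), dispatches each evaluable signature to its scoring
#' method, fills \code{external} biomarkers from the cohort's precomputed
#' columns, and returns the biomarker x sample \linkS4class{BiomarkerScores}
#' with the per-signature coverage report attached. Deterministic: the same
#' cohort always yields bitwise-identical scores.
#'
#' @param cohort an \linkS4class{IcbCohort}, or a plain expression matrix.
#' @param registry a \linkS4class{SignatureRegistry}.
#' @param params list from \code{\link{enrichmentParams}}.
#' @return a \linkS4class{BiomarkerScores}.
#' @examples
#' cohort <- simulateCohort(simConfig(n_datasets = 1, n_samples = 12,
#'                                    seed = 7))
#' sc <- scoreAll(cohort, loadSignatureDefinitions())
#' scoreMatrix(sc)[c("CYT", "IMPRES"), 1:3]
#' @export
scoreAll <- function(cohort, registry, params = enrichmentParams()) {
    if (methods::is(cohort, "IcbCohort")) {
        expr <- assay(cohort, "logtpm")
        ext <- externalScores(cohort)
    } else {
        expr <- cohort
        ext <- NULL
    }
    thr <- params$coverage_threshold
    cov_rows <- list()
    scores <- matrix(NA_real_, length(registry), ncol(expr),
                     dimnames = list(unname(signatureIds(registry)),
                                     colnames(expr)))
    for (sig in as.list(registry)) {
        cov <- validateSignatureCoverage(sig, expr, thr)
        subsets_ok <- TRUE
        if (sig@method %in% c("ssgsea", "gsva_mean") &&
            length(sig@geneSets) > 1L)
            subsets_ok <- all(vapply(sig@geneSets, function(gs)
                mean(gs %in% rownames(expr)) >= thr, logical(1)))
        cov$evaluable <- cov$evaluable && subsets_ok
        cov_rows[[sig@id]] <- cov
        if (cov$evaluable)
            scores[sig@id, ] <- .scoreOne(sig, expr, ext, params)
        else
            message("signature '", sig@id,
                    "' not evaluable (gene coverage ",
                    sprintf("%.2f", cov$fraction), "); emitting NA")
    }
    methods::new("BiomarkerScores", scores = scores,
                 coverage = do.call(rbind, unname(cov_rows)),
                 params = params)
}

#' Write a biomarker score matrix as tab-delimited text
#'
#' Missing (non-evaluable) scores are written as \code{"NA"}; a JSON
#' sidecar carries the coverage report and scoring parameters.
#'
#' @param scores a \linkS4class{BiomarkerScores}.
#' @param path output .tsv path; the sidecar is \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeScoreMatrix <- function(scores, path) {
    m <- scoreMatrix(scores)
    lines <- c(paste(c("biomarker", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                   paste(c(rownames(m)[i],
                           ifelse(is.na(m[i, ]), "NA",
                                  formatC(m[i, ], digits = 17,
                                          format = "g"))),
                         collapse = "\t"), character(1)))
    writeLines(lines, path)
    jsonlite::write_json(
        list(coverage = as.data.frame(coverageReport(scores)),
             params = scores@params),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}
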