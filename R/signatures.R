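#' @include AllClasses.R
NULL

#' Construct a SignatureDefinition
#'
#' @param id biomarker identifier.
#' @param category one of \code{immune_checkpoint, TIL, effector,
#'   antigen_associated, antigen_presenting, immune_resistance,
#'   comprehensive, tme}.
#' @param method scoring method: one of \code{single_gene, mean,
#'   weighted_sum, pairwise, ssgsea, gsva_mean, pc1, up_down, ips_scheme,
#'   mcp, external}.
#' @param direction +1 (higher score associates with response) or -1.
#' @param genes character vector of HGNC symbols; derived from
#'   \code{weights}/\code{pairs}/\code{geneSets} when omitted.
#' @param weights named numeric per-gene weights (weighted_sum).
#' @param pairs two-column matrix or list of length-2 vectors of ordered
#'   gene pairs (pairwise); a pair scores 1 when the first gene's
#'   expression strictly exceeds the second's.
#' @param geneSets named list of gene vectors.
#' @param extra free-form list (scheme constants, training_datasets, notes).
#' @return a \linkS4class{SignatureDefinition}.
#' @examples
#' SignatureDefinition("CYT", "effector", "mean", 1, c("GZMA", "PRF1"))
#' @export
SignatureDefinition <- function(id, category, method, direction,
                                genes = character(), weights = numeric(),
                                pairs = NULL, geneSets = list(),
                                extra = list()) {
    if (is.list(pairs))
        pairs <- do.call(rbind, lapply(pairs, function(p) {
            if (length(p) != 2L) stop("each pair must name exactly two genes")
            as.character(p)
        }))
    if (is.null(pairs))
        pairs <- matrix(character(), ncol = 2L)
    if (!length(genes)) {
        genes <- unique(c(names(weights), as.vector(pairs),
                          unlist(geneSets, use.names = FALSE)))
    }
    if (length(weights) && is.null(names(weights)) &&
        length(weights) == length(genes))
        names(weights) <- genes
    if (!length(direction) || is.na(suppressWarnings(as.integer(direction))) ||
        !as.integer(direction) %in% c(1L, -1L))
        stop("signature '", id, "': direction must be +1 or -1")
    methods::new("SignatureDefinition", id = as.character(id),
                 category = as.character(category),
                 method = as.character(method),
                 direction = as.integer(direction),
                 genes = as.character(genes), weights = weights,
                 pairs = pairs, geneSets = geneSets, extra = extra)
}

#' Construct a SignatureRegistry from definitions
#'
#' @param ... \linkS4class{SignatureDefinition} objects, or a single list
#'   of them.
#' @return a \linkS4class{SignatureRegistry} named by signature id.
#' @export
SignatureRegistry <- function(...) {
    defs <- list(...)
    if (length(defs) == 1L && is.list(defs[[1L]]) &&
        !methods::is(defs[[1L]], "SignatureDefinition"))
        defs <- defs[[1L]]
    names(defs) <- vapply(defs, function(s) s@id, character(1))
    methods::new("SignatureRegistry", S4Vectors::SimpleList(defs))
}

#' All genes a signature needs on the expression matrix
#'
#' Union of the flat gene list, pair members and every gene sub-set.
#'
#' @param sig a \linkS4class{SignatureDefinition}.
#' @return character vector of gene symbols (empty for external methods).
#' @export
requiredGenes <- function(sig) {
    if (sig@method == "external") return(character())
    unique(c(sig@genes, as.vector(sig@pairs),
             unlist(sig@geneSets, use.names = FALSE)))
}

#' Load signature definitions from a YAML config
#'
#' The config is a mapping with a top-level \code{signatures:} sequence;
#' each entry declares \code{id}, \code{category}, \code{method},
#' \code{direction} and whichever of \code{genes}, \code{weights},
#' \code{pairs}, \code{gene_sets}, \code{extra} its method needs. The
#' packaged default config transcribes the 22 published biomarkers plus the
#' 10 MCP-counter populations.
#'
#' @param path YAML file path; defaults to the packaged registry.
#' @return a \linkS4class{SignatureRegistry}.
#' @examples
#' reg <- loadSignatureDefinitions()
#' length(reg)
#' reg[["CYT"]]
#' @export
loadSignatureDefinitions <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "signatures", "signatures.yaml",
                            package = "icbBench", mustWork = TRUE)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$signatures))
        stop("signature config must contain a 'signatures' sequence")
    defs <- lapply(cfg$signatures, function(e) {
        for (fld in c("id", "category", "method", "direction"))
            if (is.null(e[[fld]]))
                stop("signature entry without '", fld, "' field")
        if (!e$method %in% .SCORE_METHODS)
            stop("signature '", e$id, "': unknown method '", e$method, "'")
        w <- numeric()
        genes <- as.character(unlist(e$genes))
        if (!is.null(e$weights)) {
            w <- unlist(e$weights)
            if (!is.null(names(w)) && all(nzchar(names(w)))) {
                if (!length(genes)) genes <- names(w)
            } else names(w) <- genes
        }
        SignatureDefinition(
            id = e$id, category = e$category, method = e$method,
            direction = e$direction, genes = genes, weights = w,
            pairs = e$pairs,
            geneSets = lapply(e$gene_sets %||% list(), unlist),
            extra = e$extra %||% list())
    })
    ids <- vapply(defs, function(s) s@id, character(1))
    if (anyDuplicated(ids))
        stop("duplicate signature id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(defs) <- ids
    methods::new("SignatureRegistry", S4Vectors::SimpleList(defs))
}

#' Read a GMT file into plain gene sets
#'
#' @param path GMT file (set name, description, genes; tab-delimited).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    sets <- lapply(lines, function(x) x[-(1:2)])
    names(sets) <- vapply(lines, `[`, character(1), 1L)
    sets
}

#' Check a signature's gene coverage on an expression matrix
#'
#' A biomarker whose genes are not all measured is not evaluated (fraction
#' below \code{threshold} marks it non-evaluable and the scoring engine
#' emits a missing row). The default threshold of 1 requires every gene.
#'
#' @param sig a \linkS4class{SignatureDefinition}.
#' @param expr expression matrix (rownames = genes) or a character vector
#'   of measured gene symbols.
#' @param threshold minimum measured fraction in [0, 1].
#' @return one-row \code{DataFrame}: signature_id, genes_required,
#'   genes_present, fraction, evaluable.
#' @export
validateSignatureCoverage <- function(sig, expr, threshold = 1.0) {
    measured <- if (is.character(expr)) expr else rownames(expr)
    need <- requiredGenes(sig)
    n_req <- length(need)
    n_have <- sum(need %in% measured)
    fraction <- if (n_req == 0L) 1 else n_have / n_req
    S4Vectors::DataFrame(signature_id = sig@id, genes_required = n_req,
                         genes_present = n_have, fraction = fraction,
                         evaluable = fraction >= threshold)
}

#' Hypergeometric gene-overlap test between two signatures
#'
#' Upper-tail probability of observing at least the seen overlap when the
#' two gene lists are drawn independently from a universe of
#' \code{universe_size} genes.
#'
#' @param sig_a,sig_b \linkS4class{SignatureDefinition} objects.
#' @param universe_size number of genes in the sampling universe; must be
#'   at least the size of the union of the two lists.
#' @return list with \code{p_value}, \code{overlap} (shared gene symbols)
#'   and the two list sizes.
#' @export
signatureOverlapTest <- function(sig_a, sig_b, universe_size) {
    a <- unique(requiredGenes(sig_a))
    b <- unique(requiredGenes(sig_b))
    if (universe_size < length(union(a, b)))
        stop("universe smaller than the union of the two gene lists")
    k <- length(intersect(a, b))
    p <- stats::phyper(k - 1L, length(a), universe_size - length(a),
                       length(b), lower.tail = FALSE)
    list(p_value = p, overlap = sort(intersect(a, b)),
         n_a = length(a), n_b = length(b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
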