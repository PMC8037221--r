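#' @include AllClasses.R
NULL

#' Read a genes x samples expression matrix
#'
#' Reads a bulk expression matrix in log2(TPM+1) units from tab-delimited
#' text (gene symbols in the first column, sample ids in the header) or
#' MatrixMarket triplet format (with sibling \code{<stem>.genes.txt} and
#' \code{<stem>.samples.txt} index files). Duplicate gene symbols — typically
#' multi-transcript collapse artifacts — are collapsed by the per-sample
#' maximum, and the number of collapsed rows is reported via a message.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @return numeric matrix with unique gene rownames and sample colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpressionMatrix(matrix(1:6 / 2, 3, 2,
#'     dimnames = list(c("CD8A", "CD8B", "GZMA"), c("s1", "s2"))), tf)
#' readExpressionMatrix(tf)
#' @export
readExpressionMatrix <- function(path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("expression file not found: ", path)
    if (format == "tsv") {
        header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
        if (length(header) < 2L)
            stop("malformed expression header (need gene column + >=1 sample): ",
                 header[1])
        samples <- header[-1L]
        raw <- utils::read.table(path, header = TRUE, sep = "\t",
                                 row.names = NULL, check.names = FALSE,
                                 colClasses = c("character",
                                                rep("character",
                                                    length(samples))))
        genes <- raw[[1L]]
        vals <- suppressWarnings(
            vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
        if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
        if (anyNA(vals)) {
            bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
            stop(sprintf(
                "non-numeric expression value at gene '%s', sample '%s'",
                genes[bad[1L]], samples[bad[2L]]))
        }
        mat <- matrix(vals, nrow = nrow(raw),
                      dimnames = list(genes, samples))
    } else {
        m <- as.matrix(Matrix::readMM(path))
        stem <- sub("\\.mtx$", "", path)
        gfile <- paste0(stem, ".genes.txt")
        sfile <- paste0(stem, ".samples.txt")
        if (!file.exists(gfile) || !file.exists(sfile))
            stop("mtx input needs sibling index files: ", gfile, ", ", sfile)
        rownames(m) <- readLines(gfile)
        colnames(m) <- readLines(sfile)
        mat <- m
    }
    collapseDuplicateGenes(mat)
}

#' @rdname readExpressionMatrix
#' @param mat numeric matrix with possibly duplicated rownames.
#' @export
collapseDuplicateGenes <- function(mat) {
    dup <- duplicated(rownames(mat))
    if (!any(dup)) return(mat)
    n_dup <- sum(dup)
    genes <- unique(rownames(mat))
    out <- t(vapply(genes, function(g) {
        rows <- mat[rownames(mat) == g, , drop = FALSE]
        apply(rows, 2L, max)
    }, numeric(ncol(mat))))
    if (ncol(mat) == 1L) out <- matrix(out, ncol = 1L,
                                       dimnames = list(genes,
                                                       colnames(mat)))
    colnames(out) <- colnames(mat)
    message(n_dup, " duplicate gene row(s) collapsed by per-sample maximum")
    out
}

#' Write an expression matrix as tab-delimited text
#'
#' 17-significant-digit formatting so that a write/read round trip
#' reproduces the values bit-for-bit.
#'
#' @param mat numeric matrix, genes x samples.
#' @param path output file path.
#' @param gene_col header name of the gene column.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path, gene_col = "gene") {
    lines <- c(paste(c(gene_col, colnames(mat)), collapse = "\t"),
               vapply(seq_len(nrow(mat)), function(i) {
                   paste(c(rownames(mat)[i],
                           formatC(mat[i, ], digits = 17, format = "g")),
                         collapse = "\t")
               }, character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Convert TPM values to log2(TPM+1)
#'
#' @param tpm nonnegative numeric matrix or vector of TPM values.
#' @return same shape, \code{log2(tpm + 1)}.
#' @examples
#' tpmLogTransform(c(0, 1, 7))  # 0, 1, 3
#' @export
tpmLogTransform <- function(tpm) {
    if (any(tpm < 0, na.rm = TRUE))
        stop("TPM values must be nonnegative")
    log2(tpm + 1)
}

#' Read a per-sample clinical table
#'
#' Tab-delimited with required columns \code{sample_id, dataset_id, recist,
#' os_time, os_event, pfs_time, pfs_event}; optional \code{patient_id,
#' cancer_type, therapy} and any extra columns are carried through.
#' RECIST tokens are validated; empty/NA entries become \code{"missing"}.
#'
#' @param path file path.
#' @return \code{DataFrame} with rownames = sample ids.
#' @export
readClinicalTable <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    req <- c("sample_id", .CLINICAL_REQUIRED)
    absent <- setdiff(req, colnames(tab))
    if (length(absent))
        stop("clinical table lacks column(s): ", paste(absent, collapse = ", "))
    tab$recist[is.na(tab$recist) | tab$recist == ""] <- "missing"
    bad <- !tab$recist %in% .RECIST_LEVELS
    if (any(bad))
        stop("unknown RECIST token '", tab$recist[bad][1L], "' for sample ",
             tab$sample_id[bad][1L])
    if (anyDuplicated(tab$sample_id))
        stop("duplicate sample_id in clinical table")
    out <- S4Vectors::DataFrame(tab[, setdiff(colnames(tab), "sample_id"),
                                    drop = FALSE])
    rownames(out) <- tab$sample_id
    out
}

#' Align an expression matrix and clinical table into a cohort
#'
#' Restricts both components (and any external score table) to the
#' intersection of their sample ids, harmonizes sample order, and records
#' the dropped samples per side in the cohort metadata.
#'
#' @param expr numeric matrix, genes x samples, log2(TPM+1).
#' @param clinical \code{DataFrame}/data.frame with rownames = sample ids
#'   and the clinical columns of \code{\link{readClinicalTable}}.
#' @param external_scores optional data.frame/DataFrame of precomputed
#'   per-sample biomarker columns (e.g. \code{cibersort_cd8}, \code{tide}),
#'   rownames = sample ids.
#' @return an \linkS4class{IcbCohort}; \code{metadata(x)$dropped} lists the
#'   samples dropped on each side.
#' @export
alignCohort <- function(expr, clinical, external_scores = NULL) {
    clinical <- S4Vectors::DataFrame(clinical)
    shared <- intersect(colnames(expr), rownames(clinical))
    if (length(shared) == 0L)
        stop("no shared sample ids between expression and clinical table")
    dropped <- list(expression = setdiff(colnames(expr), shared),
                    clinical = setdiff(rownames(clinical), shared))
    cd <- clinical[shared, , drop = FALSE]
    ext_names <- character()
    if (!is.null(external_scores)) {
        external_scores <- S4Vectors::DataFrame(external_scores)
        ext_names <- colnames(external_scores)
        for (nm in ext_names)
            cd[[nm]] <- external_scores[match(shared,
                                              rownames(external_scores)), nm]
    }
    se <- SummarizedExperiment(
        assays = list(logtpm = expr[, shared, drop = FALSE]),
        colData = cd)
    out <- methods::new("IcbCohort", se)
    metadata(out)$dropped <- dropped
    metadata(out)$external_score_names <- ext_names
    validObject(out)
    out
}

#' Z-score each gene across samples
#'
#' Centers and scales every gene row to mean 0 and population (divisor n)
#' standard deviation 1. Zero-variance rows are set to all-zero and their
#' names attached as attribute \code{"flagged"}.
#'
#' @param expr numeric matrix with at least two columns.
#' @return matrix of the same shape.
#' @export
zScoreGenes <- function(expr) {
    if (ncol(expr) < 2L)
        stop("z-scoring needs at least two samples")
    mu <- rowMeans(expr)
    centered <- expr - mu
    sdev <- sqrt(rowMeans(centered^2))
    flagged <- rownames(expr)[sdev == 0]
    sdev[sdev == 0] <- 1
    out <- centered / sdev
    out[rownames(out) %in% flagged, ] <- 0
    attr(out, "flagged") <- flagged
    out
}
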