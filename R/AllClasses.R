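#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom S4Vectors SimpleList DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
NULL

.SCORE_METHODS <- c("single_gene", "mean", "weighted_sum", "pairwise",
                    "ssgsea", "gsva_mean", "pc1", "up_down", "ips_scheme",
                    "mcp", "external")

.SIG_CATEGORIES <- c("immune_checkpoint", "TIL", "effector",
                     "antigen_associated", "antigen_presenting",
                     "immune_resistance", "comprehensive", "tme")

.RECIST_LEVELS <- c("CR", "PR", "SD", "PD", "missing")

#' SignatureDefinition: one biomarker's recipe
#'
#' Holds everything needed to score one transcriptomic biomarker: the scoring
#' method, the member genes (HGNC symbols), optional per-gene weights, ordered
#' gene pairs for pairwise scores, named gene sub-sets for enrichment and
#' scheme-based scores, and the documented direction of correlation with ICB
#' response (+1 higher score = more likely responder, -1 the reverse).
#'
#' @slot id biomarker identifier, e.g. "CYT".
#' @slot category one of the seven biomarker categories, or "tme" for
#'   cell-population abundances.
#' @slot method scoring method dispatch token.
#' @slot direction integer +1 or -1.
#' @slot genes character vector of HGNC gene symbols.
#' @slot weights named numeric weights aligned with \code{genes}
#'   (weighted-sum method), else length 0.
#' @slot pairs two-column character matrix of ordered gene pairs (pairwise
#'   method); a pair counts when column 1 exceeds column 2.
#' @slot geneSets named list of gene vectors (enrichment subsets, up/down
#'   programs, scheme components).
#' @slot extra free-form list: scheme constants, training-dataset ids,
#'   citation notes.
#' @exportClass SignatureDefinition
setClass("SignatureDefinition",
         representation(id = "character", category = "character",
                        method = "character", direction = "integer",
                        genes = "character", weights = "numeric",
                        pairs = "matrix", geneSets = "list",
                        extra = "list"))

setValidity("SignatureDefinition", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (!object@method %in% .SCORE_METHODS)
        msg <- c(msg, sprintf("unknown method '%s'", object@method))
    if (!object@category %in% .SIG_CATEGORIES)
        msg <- c(msg, sprintf("unknown category '%s'", object@category))
    if (length(object@direction) != 1L || !object@direction %in% c(1L, -1L))
        msg <- c(msg, "'direction' must be +1 or -1")
    if (object@method != "external" && length(object@genes) == 0L)
        msg <- c(msg, "'genes' must be non-empty unless method = 'external'")
    if (object@method == "weighted_sum" &&
        length(object@weights) != length(object@genes))
        msg <- c(msg, "'weights' must align 1:1 with 'genes'")
    if (object@method == "pairwise" && nrow(object@pairs) < 1L)
        msg <- c(msg, "pairwise signatures need at least one gene pair")
    if (object@method == "up_down" &&
        (!all(c("up", "down") %in% names(object@geneSets)) ||
         length(object@geneSets$up) == 0L || length(object@geneSets$down) == 0L))
        msg <- c(msg, "up_down signatures need non-empty 'up' and 'down' sets")
    if (length(msg)) msg else TRUE
})

#' SignatureRegistry: a validated collection of signature definitions
#'
#' A \linkS4class{SimpleList} of \linkS4class{SignatureDefinition} objects
#' with unique ids.
#'
#' @exportClass SignatureRegistry
setClass("SignatureRegistry", contains = "SimpleList",
         prototype = prototype(elementType = "SignatureDefinition"))

setValidity("SignatureRegistry", function(object) {
    ids <- vapply(object, function(s) s@id, character(1))
    if (anyDuplicated(ids))
        return(sprintf("duplicate signature id(s): %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (!identical(unname(names(object)), unname(ids)) && length(object))
        return("registry names must equal signature ids")
    TRUE
})

#' IcbCohort: an aligned expression + clinical cohort
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"logtpm"}
#' holds log2(TPM+1) expression (genes x samples) and whose \code{colData}
#' carries the per-sample clinical annotation (dataset id, RECIST category,
#' OS/PFS times and event flags, cancer type, therapy) plus any precomputed
#' external biomarker columns (e.g. \code{cibersort_cd8}, \code{tide}).
#'
#' @exportClass IcbCohort
setClass("IcbCohort", contains = "SummarizedExperiment")

.CLINICAL_REQUIRED <- c("dataset_id", "recist", "os_time", "os_event",
                        "pfs_time", "pfs_event")

setValidity("IcbCohort", function(object) {
    msg <- character()
    if (!"logtpm" %in% assayNames(object))
        msg <- c(msg, "assay 'logtpm' is required")
    else {
        x <- assay(object, "logtpm")
        if (anyNA(x) || any(!is.finite(x)))
            msg <- c(msg, "expression values must all be finite")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    absent <- setdiff(.CLINICAL_REQUIRED, colnames(colData(object)))
    if (length(absent))
        msg <- c(msg, sprintf("missing clinical column(s): %s",
                              paste(absent, collapse = ", ")))
    else {
        cd <- colData(object)
        if (!all(cd$recist %in% .RECIST_LEVELS))
            msg <- c(msg, "recist must be one of CR/PR/SD/PD/missing")
        for (fl in c("os_event", "pfs_event"))
            if (!all(cd[[fl]] %in% c(0, 1, NA)))
                msg <- c(msg, sprintf("%s must be 0/1", fl))
        for (tm in c("os_time", "pfs_time"))
            if (any(cd[[tm]] < 0, na.rm = TRUE))
                msg <- c(msg, sprintf("%s must be nonnegative", tm))
    }
    if (length(msg)) msg else TRUE
})

#' BiomarkerScores: biomarker x sample score matrix with coverage
#'
#' Rows are requested biomarkers, columns samples. Rows whose signature is
#' not fully measurable on the input matrix (per the coverage rule) are NA,
#' and the attached coverage report says why.
#'
#' @slot scores numeric matrix, biomarkers x samples; NA marks
#'   non-evaluable rows.
#' @slot coverage \code{DataFrame} with one row per requested signature:
#'   signature_id, genes_required, genes_present, fraction, evaluable.
#' @slot params list of scoring parameters used (enrichment exponent etc.).
#' @exportClass BiomarkerScores
setClass("BiomarkerScores",
         representation(scores = "matrix", coverage = "DataFrame",
                        params = "list"))

setValidity("BiomarkerScores", function(object) {
    msg <- character()
    if (!is.numeric(object@scores))
        msg <- c(msg, "'scores' must be a numeric matrix")
    if (nrow(object@coverage) &&
        !all(c("signature_id", "genes_required", "genes_present",
               "fraction", "evaluable") %in% colnames(object@coverage)))
        msg <- c(msg, "coverage report lacks required columns")
    if (length(msg)) msg else TRUE
})
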