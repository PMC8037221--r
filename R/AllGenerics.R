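#' @include AllClasses.R
NULL

#' Accessors for icbBench classes
#'
#' \code{scoreMatrix} returns the numeric biomarker x sample matrix;
#' \code{coverageReport} the per-signature coverage table;
#' \code{signatureIds} the ids housed in a registry;
#' \code{clinicalData} the clinical \code{DataFrame} of a cohort;
#' \code{externalScores} the precomputed external biomarker columns.
#'
#' @param x a \linkS4class{BiomarkerScores}, \linkS4class{SignatureRegistry}
#'   or \linkS4class{IcbCohort} object.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases scoreMatrix coverageReport signatureIds clinicalData externalScores
NULL

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("coverageReport", function(x) standardGeneric("coverageReport"))

#' @rdname accessors
#' @export
setGeneric("signatureIds", function(x) standardGeneric("signatureIds"))

#' @rdname accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname accessors
#' @export
setGeneric("externalScores", function(x) standardGeneric("externalScores"))

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "BiomarkerScores", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("coverageReport", "BiomarkerScores", function(x) x@coverage)

#' @rdname accessors
#' @export
setMethod("signatureIds", "SignatureRegistry",
          function(x) vapply(x, function(s) s@id, character(1)))

#' @rdname accessors
#' @export
setMethod("clinicalData", "IcbCohort", function(x) {
    cd <- colData(x)
    ext <- metadata(x)$external_score_names
    if (length(ext)) cd <- cd[, setdiff(colnames(cd), ext), drop = FALSE]
    cd
})

#' @rdname accessors
#' @export
setMethod("externalScores", "IcbCohort", function(x) {
    ext <- metadata(x)$external_score_names
    if (!length(ext)) return(NULL)
    colData(x)[, intersect(ext, colnames(colData(x))), drop = FALSE]
})

setMethod("show", "SignatureDefinition", function(object) {
    cat(sprintf("SignatureDefinition '%s' [%s]\n", object@id, object@category))
    cat(sprintf("  method: %s  direction: %+d\n",
                object@method, object@direction))
    cat(sprintf("  genes: %d", length(object@genes)))
    if (nrow(object@pairs)) cat(sprintf("  pairs: %d", nrow(object@pairs)))
    if (length(object@geneSets))
        cat(sprintf("  gene sets: %d", length(object@geneSets)))
    cat("\n")
})

setMethod("show", "SignatureRegistry", function(object) {
    cat(sprintf("SignatureRegistry with %d signatures\n", length(object)))
    cats <- table(vapply(object, function(s) s@category, character(1)))
    for (nm in names(cats)) cat(sprintf("  %s: %d\n", nm, cats[[nm]]))
})

setMethod("show", "BiomarkerScores", function(object) {
    cat(sprintf("BiomarkerScores: %d biomarkers x %d samples\n",
                nrow(object@scores), ncol(object@scores)))
    n_na <- sum(apply(object@scores, 1L, function(r) all(is.na(r))))
    if (n_na) cat(sprintf("  %d non-evaluable (all-NA) row(s)\n", n_na))
})
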