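#' @include AllClasses.R
NULL

.STRATEGIES <- c("PD", "OR", "OS", "DCB")

#' Assign responder / non-responder labels
#'
#' Implements the four RECIST-derived classification strategies:
#' \describe{
#'   \item{PD}{CR/PR/SD are responders; PD is the non-responder.}
#'   \item{OR}{objective response: CR/PR responders; SD/PD non-responders.}
#'   \item{OS}{CR/PR responders; SD responds only with overall survival
#'     strictly greater than one year; PD non-responder.}
#'   \item{DCB}{durable clinical benefit: CR/PR responders; SD responds
#'     only with progression-free survival strictly greater than six
#'     months; PD non-responder.}
#' }
#' Samples with RECIST \code{"missing"} are unevaluable under every
#' strategy; SD samples lacking the required survival time under OS/DCB
#' are unevaluable too. Thresholds are strict: boundary equality yields a
#' non-responder.
#'
#' @param clinical \code{DataFrame}/data.frame with columns \code{recist},
#'   \code{os_time}, \code{pfs_time} (rownames = sample ids).
#' @param strategy one of \code{"PD"}, \code{"OR"}, \code{"OS"},
#'   \code{"DCB"}.
#' @param one_year,six_months the strategy thresholds expressed in the
#'   same units as the survival times (defaults assume days:
#'   365.25 and 182.625).
#' @return character vector (named by sample) with values
#'   \code{"responder"}, \code{"non_responder"}, \code{"unevaluable"}.
#' @examples
#' cl <- data.frame(recist = c("CR", "SD", "SD", "PD"),
#'                  os_time = c(500, 400, 100, 90),
#'                  pfs_time = c(400, 120, 50, 30),
#'                  row.names = paste0("s", 1:4))
#' assignResponseLabels(cl, "OS")
#' @export
assignResponseLabels <- function(clinical, strategy = .STRATEGIES,
                                 one_year = 365.25,
                                 six_months = 182.625) {
    strategy <- match.arg(strategy)
    recist <- as.character(clinical$recist)
    recist[is.na(recist)] <- "missing"
    bad <- !recist %in% .RECIST_LEVELS
    if (any(bad))
        stop("unknown RECIST token '", recist[bad][1L], "' for sample ",
             rownames(clinical)[bad][1L])
    lab <- rep("unevaluable", length(recist))
    lab[recist %in% c("CR", "PR")] <- "responder"
    lab[recist == "PD"] <- "non_responder"
    sd_idx <- recist == "SD"
    if (strategy == "PD") {
        lab[sd_idx] <- "responder"
    } else if (strategy == "OR") {
        lab[sd_idx] <- "non_responder"
    } else {
        tm <- if (strategy == "OS") clinical$os_time else clinical$pfs_time
        thr <- if (strategy == "OS") one_year else six_months
        lab[sd_idx & !is.na(tm) & tm > thr] <- "responder"
        lab[sd_idx & !is.na(tm) & tm <= thr] <- "non_responder"
        lab[sd_idx & is.na(tm)] <- "unevaluable"
    }
    stats::setNames(lab, rownames(clinical))
}

#' Objective response rate
#'
#' (CR + PR) / (CR + PR + SD + PD); samples with missing RECIST are
#' excluded from both numerator and denominator.
#'
#' @param clinical \code{DataFrame}/data.frame with a \code{recist} column,
#'   or a character vector of RECIST tokens.
#' @return a single value in [0, 1].
#' @export
objectiveResponseRate <- function(clinical) {
    recist <- if (is.character(clinical)) clinical
              else as.character(clinical$recist)
    recist[is.na(recist)] <- "missing"
    evaluable <- recist %in% c("CR", "PR", "SD", "PD")
    if (!any(evaluable))
        stop("no sample with a RECIST category; ORR undefined")
    sum(recist %in% c("CR", "PR")) / sum(evaluable)
}

#' Write response labels as tab-delimited text
#'
#' @param labels named character vector from
#'   \code{\link{assignResponseLabels}}.
#' @param strategy the strategy that produced them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResponseLabels <- function(labels, strategy, path) {
    utils::write.table(
        data.frame(sample_id = names(labels), strategy = strategy,
                   label = unname(labels)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
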