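#' @include AllClasses.R scoring.R labels.R evaluation.R survival.R
NULL

.tryNum <- function(expr) tryCatch(expr, error = function(e) NULL)

#' Run the full biomarker benchmark over a multi-dataset cohort
#'
#' Orchestrates score -> label -> evaluate -> survive -> aggregate per
#' dataset: coverage-aware scoring of every registry biomarker, responder
#' labeling under the chosen strategy (default PD), Wilcoxon and logistic
#' association, direction-oriented ROC/AUC with median-split sensitivity
#' and specificity, Fisher's exact ORR association on datasets with more
#' than 20 evaluable patients, Kaplan-Meier/log-rank survival on
#' patient-deduplicated data, sample-size-weighted prediction scores
#' overall and per cancer-type/therapy stratum (training datasets
#' excluded per signature config), and Spearman correlation clustering of
#' the pooled score matrix. Scoring never reads clinical fields, so
#' switching the labeling strategy cannot change the score matrix. The
#' pipeline is deterministic given its inputs.
#'
#' @param cohort an \linkS4class{IcbCohort}; its \code{dataset_id} column
#'   partitions samples into benchmark datasets. A list of cohorts is
#'   also accepted and treated as one dataset each.
#' @param registry a \linkS4class{SignatureRegistry}.
#' @param strategy labeling strategy, one of \code{"PD"}, \code{"OR"},
#'   \code{"OS"}, \code{"DCB"}.
#' @param params scoring parameters from \code{\link{enrichmentParams}}.
#' @param min_fisher_n minimum evaluable patients for the ORR association
#'   (default 21, i.e. more than 20).
#' @param landmark_time landmark survival time (same units as the
#'   survival columns; default 168 days = 24 weeks).
#' @param one_year,six_months strategy thresholds in survival-time units.
#' @return an object of class \code{icbBenchReport}: a list with
#'   \code{eval}, \code{prediction}, \code{survival}, \code{orr},
#'   \code{correlation}, \code{scores}, \code{labels}, \code{log},
#'   \code{meta}.
#' @export
runBenchmark <- function(cohort, registry = loadSignatureDefinitions(),
                         strategy = "PD", params = enrichmentParams(),
                         min_fisher_n = 21L, landmark_time = 168,
                         one_year = 365.25, six_months = 182.625) {
    datasets <- if (is.list(cohort)) cohort else {
        ids <- unique(colData(cohort)$dataset_id)
        stats::setNames(lapply(ids, function(d)
            cohort[, colData(cohort)$dataset_id == d]), ids)
    }
    if (is.null(names(datasets)))
        names(datasets) <- vapply(datasets, function(co)
            as.character(colData(co)$dataset_id[1L]), character(1))
    log_lines <- character()
    eval_rows <- list(); surv_rows <- list(); orr_rows <- list()
    score_mats <- list(); labels_all <- list()
    for (ds in names(datasets)) {
        co <- datasets[[ds]]
        cl <- clinicalData(co)
        sc <- suppressMessages(scoreAll(co, registry, params))
        cov <- coverageReport(sc)
        skipped <- cov$signature_id[!cov$evaluable]
        if (length(skipped))
            log_lines <- c(log_lines, sprintf(
                "[%s] coverage skip: %s", ds,
                paste(skipped, collapse = ", ")))
        m <- scoreMatrix(sc)
        score_mats[[ds]] <- m
        labels <- assignResponseLabels(cl, strategy, one_year, six_months)
        labels_all[[ds]] <- labels
        y <- ifelse(labels == "responder", 1L,
                    ifelse(labels == "non_responder", 0L, NA_integer_))
        obj <- ifelse(cl$recist %in% c("CR", "PR"), 1L,
                      ifelse(cl$recist %in% c("SD", "PD"), 0L,
                             NA_integer_))
        clin_surv <- dedupeIfPossible(cl)
        for (bm in rownames(m)) {
            s <- m[bm, ]
            dirn <- registry[[bm]]@direction
            ok <- !is.na(s) & !is.na(y)
            if (!any(ok) || all(is.na(s))) next
            sv <- s[ok]; yv <- y[ok]
            n1 <- sum(yv == 1L); n0 <- sum(yv == 0L)
            wt <- la <- ra <- ss <- NULL
            if (n1 > 0L && n0 > 0L) {
                wt <- .tryNum(wilcoxonResponseTest(sv[yv == 1L],
                                                   sv[yv == 0L]))
                la <- .tryNum(logisticAssociation(sv, yv))
                ra <- .tryNum(rocAuc(sv, yv, dirn))
                ss <- .tryNum(sensitivitySpecificityAtMedian(sv, yv, dirn))
            }
            eval_rows[[length(eval_rows) + 1L]] <- data.frame(
                biomarker_id = bm, dataset_id = ds,
                n_responders = n1, n_non_responders = n0,
                wilcoxon_p = if (!is.null(wt)) wt$p_reported else NA_real_,
                wilcoxon_p_raw = if (!is.null(wt)) wt$p_raw else NA_real_,
                direction = dirn,
                logistic_or = if (!is.null(la)) la$or else NA_real_,
                logistic_ci_low = if (!is.null(la)) la$ci[1L] else NA_real_,
                logistic_ci_high = if (!is.null(la)) la$ci[2L] else NA_real_,
                logistic_p = if (!is.null(la)) la$p else NA_real_,
                separation = if (!is.null(la)) la$separation else NA,
                auc = if (!is.null(ra)) ra$auc else NA_real_,
                auc_raw = if (!is.null(ra) && dirn == -1L) 1 - ra$auc
                          else if (!is.null(ra)) ra$auc else NA_real_,
                sensitivity_at_median = if (!is.null(ss)) ss$sensitivity
                                        else NA_real_,
                specificity_at_median = if (!is.null(ss)) ss$specificity
                                        else NA_real_)
            # objective-response association (eligible datasets only)
            okf <- !is.na(s) & !is.na(obj)
            fr <- .tryNum(fisherOrrAssociation(s[okf], obj[okf],
                                               min_fisher_n))
            if (!is.null(fr)) {
                if (!fr$eligible)
                    log_lines <- c(log_lines, sprintf(
                        "[%s] %s: ORR association ineligible (n = %d <= %d)",
                        ds, bm, fr$n, min_fisher_n - 1L))
                orr_rows[[length(orr_rows) + 1L]] <- data.frame(
                    biomarker_id = bm, dataset_id = ds, n = fr$n,
                    eligible = fr$eligible,
                    fisher_p = if (fr$eligible) fr$p else NA_real_,
                    orr = .tryNum(objectiveResponseRate(
                        as.character(cl$recist[okf]))) %||% NA_real_)
            }
            for (ep in c("OS", "PFS")) {
                bs <- .tryNum(biomarkerSurvival(
                    s[rownames(clin_surv)], clin_surv, ep, landmark_time))
                if (is.null(bs)) next
                if (isTRUE(bs$degenerate)) {
                    log_lines <- c(log_lines, sprintf(
                        "[%s] %s %s: degenerate median split", ds, bm, ep))
                    next
                }
                surv_rows[[length(surv_rows) + 1L]] <- data.frame(
                    biomarker_id = bm, dataset_id = ds, endpoint = ep,
                    logrank_chisq = bs$logrank$chisq,
                    logrank_p = bs$logrank$p,
                    significant = bs$significant,
                    median_high = bs$km_high$median,
                    median_low = bs$km_low$median,
                    landmark_rate_high = bs$km_high$landmark$rate,
                    landmark_rate_low = bs$km_low$landmark$rate)
            }
        }
    }
    eval_df <- if (length(eval_rows)) do.call(rbind, eval_rows)
               else stop("no evaluable biomarker in any dataset")
    ds_meta <- data.frame(
        dataset_id = names(datasets),
        n = vapply(datasets, ncol, integer(1)),
        cancer_type = vapply(datasets, function(co)
            as.character(colData(co)$cancer_type[1L] %||% "other"),
            character(1)),
        therapy = vapply(datasets, function(co)
            as.character(colData(co)$therapy[1L] %||% "mixed"),
            character(1)))
    pred_df <- .predictionTable(eval_df, ds_meta, registry)
    pooled <- do.call(cbind, score_mats)
    corr <- .tryNum(suppressWarnings(
        biomarkerCorrelationClustering(pooled)))
    structure(list(
        eval = eval_df,
        prediction = pred_df,
        survival = if (length(surv_rows)) do.call(rbind, surv_rows)
                   else data.frame(),
        orr = if (length(orr_rows)) do.call(rbind, orr_rows)
              else data.frame(),
        correlation = corr,
        scores = score_mats,
        labels = labels_all,
        log = log_lines,
        meta = list(strategy = strategy, params = params,
                    datasets = ds_meta,
                    n_signatures = length(registry))),
        class = "icbBenchReport")
}

dedupeIfPossible <- function(cl) {
    if ("patient_id" %in% colnames(cl))
        suppressWarnings(dedupePatients(cl))
    else cl
}

.predictionTable <- function(eval_df, ds_meta, registry) {
    eval_df <- merge(eval_df, ds_meta, by = "dataset_id")
    strata <- rbind(
        data.frame(stratum_type = "overall", stratum = "overall"),
        unique(data.frame(stratum_type = "cancer_type",
                          stratum = ds_meta$cancer_type)),
        unique(data.frame(stratum_type = "therapy",
                          stratum = ds_meta$therapy)))
    rows <- list()
    for (bm in unique(eval_df$biomarker_id)) {
        training <- unlist(registry[[bm]]@extra$training_datasets)
        sub <- eval_df[eval_df$biomarker_id == bm & !is.na(eval_df$auc), ]
        for (k in seq_len(nrow(strata))) {
            st <- strata[k, ]
            keep <- if (st$stratum_type == "overall") rep(TRUE, nrow(sub))
                    else sub[[st$stratum_type]] == st$stratum
            ent <- sub[keep & !sub$dataset_id %in% training, ]
            if (!nrow(ent)) next
            n_eval <- ent$n_responders + ent$n_non_responders
            rows[[length(rows) + 1L]] <- data.frame(
                biomarker_id = bm, stratum_type = st$stratum_type,
                stratum = st$stratum, n_datasets = nrow(ent),
                total_n = sum(n_eval),
                prediction_score = predictionScore(ent$auc, n_eval))
        }
    }
    if (length(rows)) do.call(rbind, rows) else data.frame()
}

#' Write a benchmark report to disk
#'
#' Tab-delimited tables (missing values written as \code{"NA"}, never
#' empty cells), one JSON summary and a plain-text log. Output is
#' byte-identical for identical reports: no timestamps or environment
#' state are recorded.
#'
#' @param report an \code{icbBenchReport} from \code{\link{runBenchmark}}.
#' @param out_dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
writeReport <- function(report, out_dir) {
    stopifnot(inherits(report, "icbBenchReport"))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
        path <- file.path(out_dir, name)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
        path
    }
    paths <- c(wt(report$eval, "eval_results.tsv"),
               wt(report$prediction, "prediction_scores.tsv"),
               wt(report$survival, "survival_results.tsv"),
               wt(report$orr, "orr_results.tsv"))
    if (!is.null(report$correlation)) {
        cpath <- file.path(out_dir, "correlation_matrix.tsv")
        rho <- report$correlation$rho
        utils::write.table(
            cbind(biomarker = rownames(rho), as.data.frame(rho)),
            cpath, sep = "\t", quote = FALSE, row.names = FALSE,
            na = "NA")
        paths <- c(paths, cpath)
    }
    jpath <- file.path(out_dir, "summary.json")
    jsonlite::write_json(list(
        strategy = report$meta$strategy,
        datasets = report$meta$datasets,
        n_signatures = report$meta$n_signatures,
        n_eval_rows = nrow(report$eval),
        params = report$meta$params), jpath,
        auto_unbox = TRUE, digits = NA)
    lpath <- file.path(out_dir, "run_log.txt")
    writeLines(report$log, lpath)
    invisible(c(paths, jpath, lpath))
}

#' @export
print.icbBenchReport <- function(x, ...) {
    cat("icbBenchReport\n")
    cat(sprintf("  strategy: %s\n", x$meta$strategy))
    cat(sprintf("  datasets: %d  (total n = %d)\n",
                nrow(x$meta$datasets), sum(x$meta$datasets$n)))
    cat(sprintf("  evaluation rows: %d  survival rows: %d\n",
                nrow(x$eval), nrow(x$survival)))
    invisible(x)
}
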