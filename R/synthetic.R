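#' @include AllClasses.R cohort-io.R signatures.R
NULL

#' Configuration for the synthetic multi-dataset ICB cohort generator
#'
#' The generator emulates the structure of a multi-study ICB benchmark:
#' several datasets of realistic size, a latent responder class per
#' patient, RECIST categories drawn conditionally on that class, planted
#' mean-shift effects on chosen signature genes, and exponential
#' survival with uniform censoring. Defaults are chosen to echo published
#' ICB cohorts: dataset sizes of a few dozen to ~50 patients, a ~50\%
#' responder share under PD-style labeling, an objective response rate
#' around 25\%, and planted effects sized so the corresponding biomarker
#' AUC lands near 0.65.
#'
#' @param n_datasets number of datasets.
#' @param n_samples per-dataset sample counts (recycled).
#' @param responder_fraction latent responder probability.
#' @param therapy,cancer_type per-dataset annotations (recycled).
#' @param n_genes number of background genes on top of the registry genes.
#' @param planted_signatures named numeric vector: signature id -> effect
#'   size d in units of \code{noise_sd}; responders' member-gene means are
#'   shifted by \code{+d * noise_sd} (sign flipped for direction -1
#'   signatures).
#' @param noise_sd residual SD of log2(TPM+1) expression.
#' @param responder_hazard,nonresponder_hazard exponential event hazards
#'   per day for OS (PFS uses twice each rate).
#' @param censor_horizon uniform censoring horizon in days.
#' @param recist_probs list with \code{responder} and \code{non_responder}
#'   probability vectors over (CR, PR, SD, PD).
#' @param seed RNG seed; fixed seed means bitwise-identical cohorts.
#' @param registry \linkS4class{SignatureRegistry} supplying the gene
#'   universe and planted-signature definitions.
#' @return a validated config list of class \code{icb_sim_config}.
#' @export
simConfig <- function(n_datasets = 3L,
                      n_samples = c(41L, 42L, 50L),
                      responder_fraction = 0.5,
                      therapy = c("anti_pd1", "anti_ctla4", "combination"),
                      cancer_type = c("melanoma", "melanoma", "UC"),
                      n_genes = 2000L,
                      planted_signatures = c("CYT" = 0.4, "gene.CD8" = 0.4,
                                             "IFN-gamma" = 0.4,
                                             "PD-L1" = 0.4, "EMT" = 0.4),
                      noise_sd = 1,
                      responder_hazard = 0.0008,
                      nonresponder_hazard = 0.0016,
                      censor_horizon = 1095,
                      recist_probs = list(
                          responder = c(CR = 0.15, PR = 0.35,
                                        SD = 0.5, PD = 0),
                          non_responder = c(CR = 0, PR = 0,
                                            SD = 0.2, PD = 0.8)),
                      seed = 1L,
                      registry = loadSignatureDefinitions()) {
    cfg <- list(n_datasets = as.integer(n_datasets),
                n_samples = rep_len(as.integer(n_samples), n_datasets),
                responder_fraction = responder_fraction,
                therapy = rep_len(therapy, n_datasets),
                cancer_type = rep_len(cancer_type, n_datasets),
                n_genes = as.integer(n_genes),
                planted_signatures = planted_signatures,
                noise_sd = noise_sd,
                responder_hazard = responder_hazard,
                nonresponder_hazard = nonresponder_hazard,
                censor_horizon = censor_horizon,
                recist_probs = recist_probs, seed = as.integer(seed),
                registry = registry)
    for (cls in c("responder", "non_responder")) {
        p <- cfg$recist_probs[[cls]]
        if (length(p) != 4L || abs(sum(p) - 1) > 1e-8 || any(p < 0))
            stop("recist_probs$", cls,
                 " must be 4 nonnegative probabilities summing to 1")
    }
    if (cfg$responder_hazard <= 0 || cfg$nonresponder_hazard <= 0)
        stop("hazards must be positive")
    if (cfg$responder_fraction < 0 || cfg$responder_fraction > 1)
        stop("responder_fraction must lie in [0, 1]")
    unknown <- setdiff(names(cfg$planted_signatures),
                       signatureIds(registry))
    if (length(unknown))
        stop("planted signature(s) not in the registry: ",
             paste(unknown, collapse = ", "))
    structure(cfg, class = "icb_sim_config")
}

#' Simulate a multi-dataset ICB cohort
#'
#' Background gene expression is Gaussian in log2(TPM+1) space (gene means
#' uniform on [2, 6], SD \code{noise_sd}), truncated at 0. For each
#' planted signature, the member genes' means are shifted by
#' \code{+d * noise_sd} in latent responders (sign flipped for
#' direction -1 signatures). RECIST is drawn conditionally on the latent
#' class, OS/PFS are exponential per class with independent uniform
#' censoring. The latent class is recorded in the clinical table as
#' \code{latent_class} so recovery tests can compare against ground
#' truth. Fully reproducible from the seed; per-dataset RNG substreams
#' are derived deterministically.
#'
#' @param config from \code{\link{simConfig}}.
#' @return an \linkS4class{IcbCohort} covering all datasets.
#' @examples
#' cohort <- simulateCohort(simConfig(n_datasets = 1, n_samples = 10,
#'                                    seed = 42))
#' dim(cohort)
#' @export
simulateCohort <- function(config = simConfig()) {
    stopifnot(inherits(config, "icb_sim_config"))
    reg_genes <- unique(unlist(lapply(as.list(config$registry),
                                      requiredGenes)))
    bg_genes <- sprintf("BG%05d", seq_len(config$n_genes))
    genes <- c(reg_genes, bg_genes)
    set.seed(config$seed)
    mu <- stats::setNames(stats::runif(length(genes), 2, 6), genes)
    ds_seeds <- (config$seed + seq_len(config$n_datasets) * 10007L) %%
        .Machine$integer.max
    expr_list <- list()
    clin_list <- list()
    for (i in seq_len(config$n_datasets)) {
        set.seed(ds_seeds[i])
        n <- config$n_samples[i]
        ids <- sprintf("ds%d_s%03d", i, seq_len(n))
        latent <- stats::rbinom(n, 1L, config$responder_fraction)
        x <- matrix(stats::rnorm(length(genes) * n, mean = mu,
                                 sd = config$noise_sd),
                    nrow = length(genes),
                    dimnames = list(genes, ids))
        for (sig_id in names(config$planted_signatures)) {
            sig <- config$registry[[sig_id]]
            d <- config$planted_signatures[[sig_id]]
            shift <- d * config$noise_sd * sig@direction
            members <- intersect(requiredGenes(sig), genes)
            x[members, latent == 1L] <- x[members, latent == 1L] + shift
        }
        x <- pmax(x, 0)
        recist <- character(n)
        for (cls in c(1L, 0L)) {
            p <- config$recist_probs[[if (cls == 1L) "responder"
                                      else "non_responder"]]
            idx <- latent == cls
            if (any(idx))
                recist[idx] <- sample(c("CR", "PR", "SD", "PD"), sum(idx),
                                      replace = TRUE, prob = p)
        }
        haz <- ifelse(latent == 1L, config$responder_hazard,
                      config$nonresponder_hazard)
        os_t <- stats::rexp(n, rate = haz)
        pfs_t <- stats::rexp(n, rate = 2 * haz)
        cens_os <- stats::runif(n, 0, config$censor_horizon)
        cens_pfs <- stats::runif(n, 0, config$censor_horizon)
        clin_list[[i]] <- S4Vectors::DataFrame(
            patient_id = ids,
            dataset_id = sprintf("sim_ds%d", i),
            cancer_type = config$cancer_type[i],
            therapy = config$therapy[i],
            recist = recist,
            os_time = pmin(os_t, cens_os),
            os_event = as.integer(os_t <= cens_os),
            pfs_time = pmin(pfs_t, cens_pfs),
            pfs_event = as.integer(pfs_t <= cens_pfs),
            latent_class = latent,
            row.names = ids)
        expr_list[[i]] <- x
    }
    expr <- do.call(cbind, expr_list)
    clinical <- do.call(rbind, clin_list)
    alignCohort(expr, clinical)
}

#' Analytic AUC for a planted k-gene mean signature
#'
#' For a k-gene mean score of independent Gaussians whose means are all
#' shifted by \code{d} SD units in responders, the binormal AUC is
#' \eqn{\Phi(d \sqrt{k} / \sqrt{2})}.
#'
#' @param d per-gene effect size in SD units.
#' @param k number of signature genes.
#' @return the expected AUC.
#' @examples
#' expectedPlantedAuc(0, 4)   # 0.5
#' expectedPlantedAuc(1, 4)   # ~0.921
#' @export
expectedPlantedAuc <- function(d, k) {
    stopifnot(is.finite(d), k >= 1)
    stats::pnorm(d * sqrt(k) / sqrt(2))
}

#' Write a cohort in the formats the readers consume
#'
#' Emits \code{expression.tsv} (17-significant-digit, round-trip exact)
#' and \code{clinical.tsv} under \code{dir}.
#'
#' @param cohort an \linkS4class{IcbCohort}.
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    epath <- file.path(dir, "expression.tsv")
    cpath <- file.path(dir, "clinical.tsv")
    writeExpressionMatrix(assay(cohort, "logtpm"), epath)
    cl <- as.data.frame(clinicalData(cohort))
    cl <- cbind(sample_id = rownames(cl), cl)
    num <- vapply(cl, is.numeric, logical(1))
    cl[num] <- lapply(cl[num], function(x)
        formatC(x, digits = 17, format = "g"))
    utils::write.table(cl, cpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(expression = epath, clinical = cpath))
}
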