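# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately use the most literal
# formulation (pair loops, explicit enumeration) rather than the package's
# vectorized paths.

toyExpr <- function(n_genes = 10, n_samples = 6, seed = 1,
                    genes = sprintf("g%02d", seq_len(n_genes))) {
    set.seed(seed)
    matrix(round(runif(n_genes * n_samples, 0, 8), 3), n_genes, n_samples,
           dimnames = list(genes, sprintf("s%02d", seq_len(n_samples))))
}

toyClinical <- function(recist, os_time = NULL, pfs_time = NULL,
                        os_event = 1, pfs_event = 1,
                        dataset_id = "d1", patient_id = NULL) {
    n <- length(recist)
    ids <- sprintf("s%03d", seq_len(n))
    data.frame(recist = recist,
               dataset_id = dataset_id,
               os_time = if (is.null(os_time)) rep(100, n) else os_time,
               os_event = rep_len(os_event, n),
               pfs_time = if (is.null(pfs_time)) rep(50, n) else pfs_time,
               pfs_event = rep_len(pfs_event, n),
               patient_id = if (is.null(patient_id)) ids else patient_id,
               row.names = ids)
}

# AUC by literal pair counting: concordant + half ties over all
# responder x non-responder pairs.
bruteAuc <- function(score, y) {
    pos <- score[y == 1]
    neg <- score[y == 0]
    total <- 0
    for (a in pos) for (b in neg)
        total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    total / (length(pos) * length(neg))
}

# IMPRES by literal loop over pairs and samples.
bruteImpres <- function(expr, pairs) {
    out <- integer(ncol(expr))
    for (s in seq_len(ncol(expr))) {
        k <- 0L
        for (i in seq_len(nrow(pairs)))
            if (expr[pairs[i, 1], s] > expr[pairs[i, 2], s]) k <- k + 1L
        out[s] <- k
    }
    out
}

# Spearman rho via explicit rank-then-Pearson.
bruteSpearman <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
        sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Exact two-sided rank-sum p by enumerating all group assignments.
permWilcoxP <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    obs <- sum(rank(pooled)[seq_len(n1)])
    combs <- utils::combn(length(pooled), n1)
    stats <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
    mu <- n1 * (length(pooled) + 1) / 2
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Product-limit estimator written out step by step.
bruteKm <- function(times, events) {
    ts <- sort(unique(times[events == 1]))
    s <- 1
    out <- numeric(length(ts))
    for (i in seq_along(ts)) {
        n_at <- sum(times >= ts[i])
        d <- sum(times == ts[i] & events == 1)
        s <- s * (1 - d / n_at)
        out[i] <- s
    }
    list(time = ts, surv = out)
}

smallRegistry <- function() {
    SignatureRegistry(
        SignatureDefinition("SIG4", "effector", "mean", 1,
                            genes = c("G1", "G2", "G3", "G4")),
        SignatureDefinition("NEG2", "immune_resistance", "mean", -1,
                            genes = c("N1", "N2")))
}
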