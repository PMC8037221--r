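#' @include AllClasses.R evaluation.R
NULL

#' Exclude patients contributing more than one sample
#'
#' Survival analysis treats the patient as the unit; patients with more
#' than one sample are removed entirely. With no \code{patient_id} column
#' the table is returned unchanged with a warning.
#'
#' @param clinical \code{DataFrame}/data.frame with an optional
#'   \code{patient_id} column.
#' @return the filtered table.
#' @export
dedupePatients <- function(clinical) {
    if (!"patient_id" %in% colnames(clinical) ||
        all(is.na(clinical$patient_id))) {
        warning("no patient_id column; multi-sample patients cannot be ",
                "identified")
        return(clinical)
    }
    counts <- table(clinical$patient_id)
    multi <- names(counts)[counts > 1L]
    clinical[!clinical$patient_id %in% multi, , drop = FALSE]
}

#' Kaplan-Meier product-limit fit
#'
#' Events at a given time precede censorings at that time. The median is
#' the earliest event time where the survival curve drops to 0.5 or
#' below (undefined when never reached). The landmark survival rate at
#' \code{landmark_time} comes with a Greenwood 95\% CI on the log scale,
#' clamped to [0, 1].
#'
#' @param times nonnegative event/censoring times.
#' @param events binary event flags (1 = event, 0 = censored).
#' @param landmark_time time point for the landmark rate (same units as
#'   \code{times}); default 168 (24 weeks in days).
#' @return list with \code{time}, \code{surv}, \code{at_risk},
#'   \code{n_events} per distinct event time, plus \code{median},
#'   \code{landmark} (time, rate, ci).
#' @export
kmFit <- function(times, events, landmark_time = 168) {
    if (any(times < 0))
        stop("survival times must be nonnegative")
    stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
    n <- length(times)
    ev_times <- sort(unique(times[events == 1]))
    surv <- numeric(length(ev_times))
    at_risk <- integer(length(ev_times))
    d <- integer(length(ev_times))
    s <- 1
    gw <- 0   # running Greenwood sum of d / (n (n - d))
    gw_at <- numeric(length(ev_times))
    for (i in seq_along(ev_times)) {
        t <- ev_times[i]
        at_risk[i] <- sum(times >= t)
        d[i] <- sum(times == t & events == 1)
        s <- s * (1 - d[i] / at_risk[i])
        gw <- gw + if (at_risk[i] > d[i])
            d[i] / (at_risk[i] * (at_risk[i] - d[i])) else Inf
        surv[i] <- s
        gw_at[i] <- gw
    }
    med <- if (length(ev_times) && any(surv <= 0.5))
        ev_times[which(surv <= 0.5)[1L]] else NA_real_
    idx <- which(ev_times <= landmark_time)
    if (length(idx)) {
        i <- max(idx)
        s_lm <- surv[i]
        if (s_lm > 0 && is.finite(gw_at[i])) {
            se_log <- sqrt(gw_at[i])
            ci <- exp(log(s_lm) + c(-1, 1) * stats::qnorm(0.975) * se_log)
            ci <- pmin(pmax(ci, 0), 1)
        } else ci <- c(NA_real_, NA_real_)
    } else {
        s_lm <- 1
        ci <- c(1, 1)
    }
    list(time = ev_times, surv = surv, at_risk = at_risk, n_events = d,
         n = n, median = med,
         landmark = list(time = landmark_time, rate = s_lm, ci = ci))
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' At each distinct event time the observed events in group A are
#' compared with their hypergeometric expectation given the risk sets;
#' the squared standardized sum is referred to a chi-square with one
#' degree of freedom.
#'
#' @param times_a,events_a,times_b,events_b the two groups' times and
#'   binary event flags.
#' @return list with \code{chisq}, \code{df} (= 1), \code{p},
#'   \code{observed} and \code{expected} events in group A.
#' @export
logrankTest <- function(times_a, events_a, times_b, events_b) {
    if (!length(times_a) || !length(times_b))
        stop("both groups must be non-empty")
    times <- c(times_a, times_b)
    events <- c(events_a, events_b)
    ina <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
    ev_times <- sort(unique(times[events == 1]))
    if (!length(ev_times)) {
        warning("no events in either group; p set to 1")
        return(list(chisq = 0, df = 1L, p = 1,
                    observed = 0, expected = 0))
    }
    O <- E <- V <- 0
    for (t in ev_times) {
        at <- times >= t
        n_t <- sum(at)
        n1 <- sum(at & ina)
        d_t <- sum(times == t & events == 1)
        d1 <- sum(times == t & events == 1 & ina)
        O <- O + d1
        E <- E + d_t * n1 / n_t
        if (n_t > 1L)
            V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) *
                (n_t - d_t) / (n_t - 1)
    }
    chisq <- if (V > 0) (O - E)^2 / V else 0
    list(chisq = chisq, df = 1L,
         p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
         observed = O, expected = E)
}

#' Median-split survival comparison for one biomarker
#'
#' Splits patients at the biomarker's median score (median-tied patients
#' joining the smaller strict group), fits Kaplan-Meier curves per group,
#' compares them by log-rank, and reports landmark rates. Inputs should
#' already be deduplicated with \code{\link{dedupePatients}}.
#'
#' @param scores named numeric vector of biomarker scores (names =
#'   sample ids).
#' @param clinical \code{DataFrame}/data.frame with survival columns,
#'   rownames = sample ids.
#' @param endpoint \code{"OS"} or \code{"PFS"}.
#' @param landmark_time landmark time in the units of the survival
#'   columns (default 168 = 24 weeks in days).
#' @return list with \code{km_high}, \code{km_low}, \code{logrank},
#'   \code{significant} (p < 0.05), \code{groups}, or
#'   \code{degenerate = TRUE} when no split is possible.
#' @export
biomarkerSurvival <- function(scores, clinical, endpoint = c("OS", "PFS"),
                              landmark_time = 168) {
    endpoint <- match.arg(endpoint)
    shared <- intersect(names(scores), rownames(clinical))
    scores <- scores[shared]
    cl <- clinical[shared, , drop = FALSE]
    tm_col <- if (endpoint == "OS") "os_time" else "pfs_time"
    ev_col <- if (endpoint == "OS") "os_event" else "pfs_event"
    ok <- !is.na(scores) & !is.na(cl[[tm_col]]) & !is.na(cl[[ev_col]])
    scores <- scores[ok]; cl <- cl[ok, , drop = FALSE]
    if (length(scores) < 2L || stats::sd(scores) == 0)
        return(list(degenerate = TRUE))
    grp <- medianSplit(scores)
    if (length(unique(grp)) < 2L)
        return(list(degenerate = TRUE))
    hi <- grp == "high"
    lr <- logrankTest(cl[[tm_col]][hi], cl[[ev_col]][hi],
                      cl[[tm_col]][!hi], cl[[ev_col]][!hi])
    list(degenerate = FALSE,
         km_high = kmFit(cl[[tm_col]][hi], cl[[ev_col]][hi], landmark_time),
         km_low = kmFit(cl[[tm_col]][!hi], cl[[ev_col]][!hi],
                        landmark_time),
         logrank = lr, significant = lr$p < 0.05, groups = grp)
}
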