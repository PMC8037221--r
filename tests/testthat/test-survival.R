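test_that("multi-sample patients are removed entirely", {
    cl <- toyClinical(c("CR", "PR", "SD", "PD"),
                      patient_id = c("p1", "p1", "p2", "p3"))
    out <- dedupePatients(cl)
    expect_setequal(out$patient_id, c("p2", "p3"))

    single <- toyClinical(c("CR", "PD"))
    expect_identical(dedupePatients(single), single)
    expect_warning(dedupePatients(single[, setdiff(colnames(single),
                                                   "patient_id")]),
                   "patient_id")

    set.seed(2)
    for (k in 1:20) {
        pid <- sample(sprintf("p%d", 1:8), 15, replace = TRUE)
        cl <- toyClinical(rep("SD", 15), patient_id = pid)
        out <- dedupePatients(cl)
        keep <- names(table(pid))[table(pid) == 1]
        expect_equal(nrow(out), length(keep))
    }
})

test_that("Kaplan-Meier matches closed forms and the hand-worked censored toy", {
    none <- kmFit(c(3, 6, 9), c(0, 0, 0))
    expect_length(none$time, 0L)
    expect_true(is.na(none$median))

    all_ev <- kmFit(c(1, 2, 3), c(1, 1, 1))
    expect_equal(all_ev$surv, c(2 / 3, 1 / 3, 0))
    expect_equal(all_ev$median, 2)

    # 5-subject censored toy: events at 1, 3, 5; censorings at 2+, 4+
    toy <- kmFit(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
    expect_equal(toy$time, c(1, 3, 5))
    expect_equal(toy$surv, c(4 / 5, 4 / 5 * 2 / 3, 0))
    expect_equal(toy$at_risk, c(5L, 3L, 1L))
    expect_equal(toy$median, 5)
})

test_that("KM with no censoring equals the empirical survival function", {
    set.seed(6)
    t <- round(rexp(30, 0.1), 2)
    km <- kmFit(t, rep(1, 30))
    emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
    expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("KM and landmark agree with the survival package", {
    skip_if_not_installed("survival")
    set.seed(7)
    t <- round(rexp(40, 0.02), 1)
    e <- rbinom(40, 1, 0.7)
    km <- kmFit(t, e, landmark_time = 30)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    idx <- sf$n.event > 0
    expect_equal(km$time, sf$time[idx])
    expect_equal(km$surv, sf$surv[idx], tolerance = 1e-12)
    ref <- summary(sf, times = 30)
    expect_equal(km$landmark$rate, ref$surv, tolerance = 1e-12)
    expect_true(all(km$landmark$ci >= 0 & km$landmark$ci <= 1))
})

test_that("log-rank matches the hand-worked 3-vs-3 toy and survdiff", {
    ta <- c(1, 3, 5); tb <- c(2, 4, 6)
    ea <- eb <- c(1, 1, 1)
    # term-by-term O - E and variance at event times 1..6
    O <- E <- V <- 0
    times <- c(ta, tb); grp <- c(1, 1, 1, 0, 0, 0)
    for (t in 1:6) {
        at <- times >= t
        n_t <- sum(at); n1 <- sum(at & grp == 1)
        d <- sum(times == t)
        d1 <- sum(times == t & grp == 1)
        O <- O + d1
        E <- E + d * n1 / n_t
        if (n_t > 1)
            V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    }
    res <- logrankTest(ta, ea, tb, eb)
    expect_equal(res$observed, O)
    expect_equal(res$expected, E)
    expect_equal(res$chisq, (O - E)^2 / V, tolerance = 1e-12)

    skip_if_not_installed("survival")
    sd <- survival::survdiff(
        survival::Surv(c(ta, tb), c(ea, eb)) ~ c(1, 1, 1, 0, 0, 0))
    expect_equal(res$chisq, sd$chisq, tolerance = 1e-12)
})

test_that("log-rank is symmetric, scale-invariant and null on identical groups", {
    t <- c(2, 5, 7, 9); e <- c(1, 0, 1, 1)
    same <- logrankTest(t, e, t, e)
    expect_equal(same$chisq, 0)
    expect_equal(same$p, 1)

    set.seed(9)
    ta <- rexp(20); ea <- rbinom(20, 1, 0.8)
    tb <- rexp(25, 2); eb <- rbinom(25, 1, 0.8)
    ab <- logrankTest(ta, ea, tb, eb)
    ba <- logrankTest(tb, eb, ta, ea)
    expect_equal(ab$chisq, ba$chisq, tolerance = 1e-12)
    scaled <- logrankTest(ta * 7, ea, tb * 7, eb)
    expect_equal(ab$chisq, scaled$chisq, tolerance = 1e-12)
    expect_warning(nil <- logrankTest(1:3, c(0, 0, 0), 4:6, c(0, 0, 0)),
                   "no events")
    expect_equal(nil$p, 1)
})

test_that("biomarkerSurvival splits at the median and flags degenerate input", {
    set.seed(10)
    n <- 80
    s <- stats::setNames(rnorm(n), sprintf("s%03d", 1:n))
    cl <- toyClinical(rep("SD", n),
                      os_time = rexp(n, ifelse(s > 0, 0.005, 0.02)),
                      os_event = rbinom(n, 1, 0.8))
    res <- biomarkerSurvival(s, cl, "OS")
    expect_false(res$degenerate)
    expect_equal(sort(unique(res$groups)), c("high", "low"))
    expect_lt(res$logrank$p, 0.05)   # strong planted effect

    const <- stats::setNames(rep(1, n), names(s))
    expect_true(biomarkerSurvival(const, cl, "OS")$degenerate)
})
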