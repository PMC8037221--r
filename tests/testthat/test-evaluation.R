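test_that("wilcoxon test floors reported p and keeps the raw value", {
    set.seed(1)
    x <- rnorm(60, 5); y <- rnorm(60, 0)
    res <- wilcoxonResponseTest(x, y)
    expect_lt(res$p_raw, 1e-5)
    expect_equal(res$p_reported, 1e-5)
    expect_equal(res$direction, 1)

    same <- wilcoxonResponseTest(1:5, 1:5)
    expect_equal(same$p_raw, 1)
    expect_error(wilcoxonResponseTest(numeric(), 1:3), "non-empty")
})

test_that("small-sample wilcoxon p matches exact permutation enumeration", {
    set.seed(9)
    for (k in 1:10) {
        x <- round(rnorm(4), 2); y <- round(rnorm(4) + 1, 2)
        if (anyDuplicated(c(x, y))) next
        expect_equal(wilcoxonResponseTest(x, y)$p_raw, permWilcoxP(x, y),
                     tolerance = 1e-12)
    }
})

test_that("wilcoxon p is invariant to strictly increasing transforms", {
    set.seed(4)
    x <- runif(15, 0, 5); y <- runif(12, 1, 6)
    a <- wilcoxonResponseTest(x, y)$p_raw
    b <- wilcoxonResponseTest(exp(x), exp(y))$p_raw
    expect_equal(a, b)
})

test_that("logistic association signs follow group means and flags separation", {
    set.seed(10)
    for (k in 1:20) {
        y <- rbinom(50, 1, 0.5)
        s <- rnorm(50) + y * rnorm(1)
        if (length(unique(y)) < 2 || sd(s) == 0) next
        fit <- logisticAssociation(s, y)
        if (!fit$separation)
            expect_equal(sign(fit$coef),
                         sign(mean(s[y == 1]) - mean(s[y == 0])))
    }
    # exact threshold labels -> separation sentinel, not a crash
    s <- c(1:10)
    y <- as.integer(s > 5)
    fit <- logisticAssociation(s, y)
    expect_true(fit$separation)
    expect_equal(fit$or, Inf)
    expect_error(logisticAssociation(rep(1, 10), rbinom(10, 1, 0.5)),
                 "constant")
})

test_that("logistic Wald CI covers the null for permuted scores", {
    set.seed(11)
    cover <- 0
    n_rep <- 1000
    for (k in seq_len(n_rep)) {
        y <- c(rep(1, 20), rep(0, 20))
        s <- rnorm(40)                    # independent of label
        fit <- logisticAssociation(s, y)
        if (!fit$separation && fit$ci[1] <= 1 && fit$ci[2] >= 1)
            cover <- cover + 1
    }
    expect_gte(cover / n_rep, 0.93)
})

test_that("AUC equals brute-force pair counting and respects direction", {
    y <- c(rep(1, 4), rep(0, 4))
    expect_equal(rocAuc(c(4, 5, 6, 7, 0, 1, 2, 3), y)$auc, 1)
    expect_equal(rocAuc(rep(2, 8), y)$auc, 0.5)

    set.seed(14)
    for (k in 1:60) {
        n <- sample(6:30, 1)
        y <- c(rep(1, ceiling(n / 3)), rep(0, n - ceiling(n / 3)))
        s <- sample(round(runif(n, 0, 4), 1))   # ties likely
        expect_equal(rocAuc(s, y)$auc, bruteAuc(s, y), tolerance = 1e-12)
        expect_equal(rocAuc(s, y, -1L)$auc, bruteAuc(-s, y),
                     tolerance = 1e-12)
    }
    # tie-free scores: the two orientations sum to one
    s <- sample(seq(0.1, 2, length.out = 12))
    y <- rbinom(12, 1, 0.5); y[1] <- 1; y[2] <- 0
    expect_equal(rocAuc(s, y, 1L)$auc + rocAuc(s, y, -1L)$auc, 1)
    expect_error(rocAuc(s, rep(1, 12)), "both classes")
})

test_that("AUC agrees with pROC on a random instance", {
    skip_if_not_installed("pROC")
    set.seed(8)
    s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("prediction score is the size-weighted AUC mean", {
    expect_equal(predictionScore(c(0.6, 0.8), c(10, 30)), 0.75)
    expect_equal(predictionScore(0.67, 42), 0.67)
    expect_equal(predictionScore(c(0.6, 0.8), c(10, 30),
                                 excluded_as_training = c(TRUE, FALSE)),
                 0.8)
    expect_error(predictionScore(c(0.6), c(10), TRUE), "no dataset")
    expect_error(predictionScore(c(0.6), c(0)), "positive")

    set.seed(20)
    for (k in 1:100) {
        n <- sample(2:8, 1)
        auc <- runif(n, 0.3, 0.9)
        size <- sample(10:300, n)
        manual <- sum(auc * size) / sum(size)
        got <- predictionScore(auc, size)
        expect_equal(got, manual, tolerance = 1e-12)
        expect_gte(got, min(auc)); expect_lte(got, max(auc))
    }
    auc <- runif(4); expect_equal(predictionScore(auc, rep(7, 4)),
                                  mean(auc))
})

test_that("median split sends median-tied samples to the smaller group", {
    g <- medianSplit(c(1, 2, 2, 3, 4))
    expect_equal(sum(g == "low"), 3)
    expect_equal(sum(g == "high"), 2)
    expect_equal(unname(g), c("low", "low", "low", "high", "high"))

    # odd n distinct: median joins a (n-1)/2-sized side; even n balances
    expect_equal(table(medianSplit(c(10, 20, 30)))[["low"]], 2)
    expect_equal(as.integer(table(medianSplit(1:6))), c(3L, 3L))
    expect_error(medianSplit(rep(3, 4)), "all scores equal")
    expect_error(medianSplit(1), "at least two")
})

test_that("median split always partitions with imbalance bounded by ties", {
    set.seed(22)
    for (k in 1:1000) {
        n <- sample(2:40, 1)
        s <- sample(round(runif(n, 0, 3), sample(0:1, 1)), n, replace = TRUE)
        if (length(unique(s)) < 2) next
        g <- medianSplit(s)
        expect_equal(length(g), n)
        expect_true(all(g %in% c("high", "low")))
        n_tie <- sum(s == stats::median(s))
        expect_lte(abs(sum(g == "high") - sum(g == "low")), max(n_tie, 1))
    }
})

test_that("median-threshold sensitivity/specificity behave at the extremes", {
    y <- c(rep(1, 5), rep(0, 5))
    s <- c(6:10, 1:5)
    res <- sensitivitySpecificityAtMedian(s, y)
    expect_equal(res$sensitivity, 1)
    expect_equal(res$specificity, 1)

    flipped <- sensitivitySpecificityAtMedian(-s, y, direction = -1L)
    expect_equal(flipped$sensitivity, 1)
    expect_equal(flipped$specificity, 1)

    set.seed(30)
    y <- rbinom(2000, 1, 0.5); s <- rnorm(2000)
    res <- sensitivitySpecificityAtMedian(s, y)
    expect_lt(abs(res$sensitivity - 0.5), 0.05)
    expect_lt(abs(res$specificity - 0.5), 0.05)
})

test_that("Fisher ORR association enforces the >20-patient rule", {
    s <- c(6:10, 1:5) + runif(10, 0, 0.1)
    y <- c(rep(1, 5), rep(0, 5))
    expect_false(fisherOrrAssociation(s, y)$eligible)         # n = 10
    expect_false(fisherOrrAssociation(rep(s, 2), rep(y, 2))$eligible)  # 20
    res <- fisherOrrAssociation(c(s, rep(s, 2)), c(y, rep(y, 2)))
    expect_true(res$eligible)                                  # 30
    expect_true(res$p < 1)
})

test_that("Spearman clustering matches rank-then-Pearson and handles sign", {
    set.seed(33)
    m <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("b", 1:4), paste0("s", 1:10)))
    res <- biomarkerCorrelationClustering(m)
    for (i in 1:3) for (j in (i + 1):4)
        expect_equal(res$rho[i, j], bruteSpearman(m[i, ], m[j, ]),
                     tolerance = 1e-12)
    m2 <- rbind(a = m[1, ], mono = exp(m[1, ]), neg = -m[1, ],
                other = m[2, ])
    res2 <- biomarkerCorrelationClustering(m2)
    expect_equal(res2$rho["a", "mono"], 1)
    expect_equal(res2$rho["a", "neg"], -1)
    expect_warning(
        biomarkerCorrelationClustering(rbind(m, const = rep(1, 10))),
        "constant")
    expect_setequal(res$order, rownames(m))
})
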