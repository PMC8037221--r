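test_that("single-gene, mean and weighted-sum scores reduce to arithmetic", {
    m <- rbind(A = c(0.5, 2.0), B = c(3.5, 6.0))
    colnames(m) <- c("s1", "s2")
    expect_equal(scoreSingleGene(m, "A"), c(s1 = 0.5, s2 = 2.0))
    expect_error(scoreSingleGene(m, "ZZ"), "not measured")

    expect_equal(scoreMeanSignature(m, c("A", "B")), c(s1 = 2, s2 = 4))
    expect_equal(scoreMeanSignature(m, "A"), scoreSingleGene(m, "A"))

    expect_equal(scoreWeightedSum(m, c(A = 1, B = 1)), c(s1 = 4, s2 = 8))
    expect_equal(unname(scoreWeightedSum(m, c(A = 0, B = 0))), c(0, 0))

    r <- toyExpr(8, 5, seed = 11)
    genes <- rownames(r)[1:6]
    manual <- apply(r[genes, ], 2, function(col) sum(col) / 6)
    expect_equal(scoreMeanSignature(r, genes), manual, tolerance = 1e-12)
    w <- stats::setNames(rnorm(6), genes)
    manual_w <- apply(r[genes, ], 2, function(col) sum(w * col))
    expect_equal(scoreWeightedSum(r, w), manual_w, tolerance = 1e-12)
})

test_that("IMPRES counts strict pairwise wins and matches the loop oracle", {
    pairs <- rbind(c("A", "B"), c("C", "D"))
    m <- rbind(A = c(5, 1, 2), B = c(1, 1, 5), C = c(4, 0, 3),
               D = c(2, 3, 3))
    colnames(m) <- paste0("s", 1:3)
    got <- scoreImpres(m, pairs)
    expect_equal(unname(got), c(2L, 0L, 0L))   # ties and losses score 0

    set.seed(21)
    for (rep in 1:25) {
        r <- toyExpr(10, 4, seed = rep)
        pr <- cbind(sample(rownames(r), 5), sample(rownames(r), 5))
        expect_equal(unname(scoreImpres(r, pr)), bruteImpres(r, pr))
    }
    expect_error(scoreImpres(m, rbind(c("A", "ZZ"))), "not measured")
})

test_that("PC1 scores are centered, oriented and beat random projections", {
    # two perfectly correlated genes: score is affine in the shared profile
    prof <- c(1, 3, 2, 5, 4)
    m <- rbind(A = prof, B = 2 * prof + 1)
    colnames(m) <- paste0("s", 1:5)
    s <- scorePc1(m, c("A", "B"))
    expect_equal(abs(cor(s, prof)), 1, tolerance = 1e-12)
    expect_gt(cor(s, prof), 0)            # positive orientation
    expect_equal(mean(s), 0, tolerance = 1e-12)

    r <- toyExpr(6, 10, seed = 31)
    sc <- scorePc1(r, rownames(r))
    z <- zScoreGenes(r)
    set.seed(99)
    v_pc1 <- stats::var(sc)
    for (k in 1:200) {
        u <- rnorm(6); u <- u / sqrt(sum(u^2))
        expect_lte(stats::var(as.vector(t(z) %*% u)), v_pc1 + 1e-10)
    }
    expect_error(scorePc1(rbind(A = rep(1, 5), B = rep(2, 5)),
                          c("A", "B")), "variance")
})

test_that("up/down scores subtract centered program means", {
    m <- rbind(U1 = c(3, 1), U2 = c(5, 3), D1 = c(2, 0), D2 = c(1, 3))
    colnames(m) <- c("s1", "s2")
    centered <- m - rowMeans(m)
    manual <- colMeans(centered[c("U1", "U2"), ]) -
        colMeans(centered[c("D1", "D2"), ])
    expect_equal(scoreUpDown(m, c("U1", "U2"), c("D1", "D2")), manual)
    expect_equal(unname(scoreUpDown(m, c("U1", "U2"), c("U1", "U2"))),
                 c(0, 0))
    expect_error(scoreUpDown(m, character(), "D1"), "non-empty")
})

test_that("IPS clamps at 0 and 10 and maps the aggregate affinely", {
    sig <- SignatureDefinition(
        "IPS4", "comprehensive", "ips_scheme", 1,
        geneSets = list(m = "M1", e = "E1", s = "S1", c = "C1"),
        extra = list(component_weights = list(m = 1, e = 1, s = -1, c = -1),
                     component_category = list(m = "MHC", e = "EC",
                                               s = "SC", c = "CP"),
                     map = list(zero_at = 0, ten_at = 3)))
    m <- rbind(M1 = c(1, 2, 3, 4), E1 = c(4, 3, 2, 1),
               S1 = c(2, 2, 4, 4), C1 = c(5, 5, 1, 1))
    colnames(m) <- paste0("s", 1:4)
    got <- scoreIps(m, sig)
    z <- zScoreGenes(m)
    agg <- colMeans(rbind(z["M1", ], z["E1", ], -z["S1", ], -z["C1", ]))
    manual <- 10 * pmin(pmax(agg / 3, 0), 1)
    expect_equal(got, manual, ignore_attr = TRUE)
    expect_true(all(got >= 0 & got <= 10))
    # clamp checks on engineered aggregates
    expect_equal(unname(got[agg <= 0]), rep(0, sum(agg <= 0)))
})

test_that("MCP abundance is the marker mean, duplicates acting as weights", {
    m <- rbind(A = c(1, 5), B = c(3, 1))
    colnames(m) <- c("s1", "s2")
    expect_equal(scoreMcp(m, c("A", "B")), c(s1 = 2, s2 = 3))
    dup <- scoreMcp(m, c("A", "A", "B"))
    expect_equal(dup, (2 * m["A", ] + m["B", ]) / 3)
    reg <- loadSignatureDefinitions()
    mcp_ids <- names(reg)[vapply(reg, function(s) s@method == "mcp",
                                 logical(1))]
    expect_length(mcp_ids, 10L)
})

test_that("scoreAll applies coverage, is deterministic and label-blind", {
    cohort <- simulateCohort(simConfig(n_datasets = 1, n_samples = 10,
                                       n_genes = 100, seed = 13))
    reg <- loadSignatureDefinitions()
    sc1 <- suppressMessages(scoreAll(cohort, reg))
    sc2 <- suppressMessages(scoreAll(cohort, reg))
    expect_identical(scoreMatrix(sc1), scoreMatrix(sc2))

    # external biomarkers without input columns are missing, all else scored
    na_rows <- rownames(scoreMatrix(sc1))[apply(scoreMatrix(sc1), 1,
                                                function(r) all(is.na(r)))]
    expect_setequal(na_rows, c("CIBERSORT.CD8", "TIDE"))

    # dropping CD8B kills gene.CD8 at the default threshold
    expr <- SummarizedExperiment::assay(cohort, "logtpm")
    expr2 <- expr[setdiff(rownames(expr), "CD8B"), ]
    sc3 <- suppressMessages(scoreAll(expr2, reg))
    expect_true(all(is.na(scoreMatrix(sc3)["gene.CD8", ])))
    expect_false(coverageReport(sc3)[
        coverageReport(sc3)$signature_id == "gene.CD8", "evaluable"])
    expect_false(anyNA(scoreMatrix(sc3)["CYT", ]))
})

test_that("all score families are permutation-equivariant in samples", {
    cohort <- simulateCohort(simConfig(n_datasets = 1, n_samples = 8,
                                       n_genes = 60, seed = 17))
    reg <- loadSignatureDefinitions()
    sc <- scoreMatrix(suppressMessages(scoreAll(cohort, reg)))
    set.seed(5)
    perm <- sample(ncol(cohort))
    sc_p <- scoreMatrix(suppressMessages(scoreAll(cohort[, perm], reg)))
    expect_equal(sc_p, sc[, perm], tolerance = 1e-12)
})

test_that("rank-based families are monotone-invariant, means are not", {
    r <- toyExpr(12, 5, seed = 41)
    set <- rownames(r)[c(2, 5, 7)]
    pairs <- cbind(rownames(r)[1:3], rownames(r)[4:6])
    r3 <- r^3                     # strictly increasing on positive values
    expect_equal(ssgseaScores(r, set), ssgseaScores(r3, set))
    expect_equal(scoreImpres(r, pairs), scoreImpres(r3, pairs))
    expect_false(isTRUE(all.equal(scoreMeanSignature(r, set),
                                  scoreMeanSignature(r3, set))))
    expect_false(isTRUE(all.equal(
        scoreWeightedSum(r, stats::setNames(c(1, 2, 3), set)),
        scoreWeightedSum(r3, stats::setNames(c(1, 2, 3), set)))))
})

test_that("TIS columns average to zero and match the manual pipeline", {
    r <- toyExpr(20, 6, seed = 55)
    sets <- list(a = rownames(r)[1:4], b = rownames(r)[5:8],
                 c = rownames(r)[9:12])
    tis <- scoreTis(r, sets)
    expect_equal(mean(tis), 0, tolerance = 1e-12)

    es <- t(sapply(sets, function(gs) ssgseaScores(r, gs)))
    zs <- (es - rowMeans(es)) /
        sqrt(rowMeans((es - rowMeans(es))^2))
    expect_equal(tis, colMeans(zs), tolerance = 1e-12)

    # identical samples get identical TIS
    r2 <- cbind(r, dup = r[, 1])
    colnames(r2)[ncol(r2)] <- "dup"
    tis2 <- scoreTis(r2, sets)
    expect_equal(unname(tis2["dup"]), unname(tis2[colnames(r)[1]]))
})
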