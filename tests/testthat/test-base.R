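test_that("perfect concentration at the top or bottom saturates the deviation", {
    genes <- paste0("g", 1:8)
    rp <- rankProfile(setNames(8:1, genes))
    expect_equal(as.numeric(runningSumDeviation(rp, setNames(rep(1, 3),
                                                             genes[1:3]))),
                 1.0)
    expect_equal(as.numeric(runningSumDeviation(rp, setNames(rep(1, 3),
                                                             genes[6:8]))),
                 -1.0)
    # empty profile is degenerate, full support has no background
    d0 <- runningSumDeviation(rp, setNames(numeric(0), character(0)))
    expect_equal(as.numeric(d0), 0)
    expect_true(attr(d0, "degenerate"))
    expect_error(runningSumDeviation(rp, setNames(rep(1, 8), genes)),
                 "background")
})

test_that("the 8-gene worked example matches the exhaustive scan exactly", {
    genes <- paste0("g", 1:8)
    rp <- rankProfile(setNames(8:1, genes))
    profile <- setNames(c(1.0, 0.5, 0.25), c("g2", "g5", "g7"))
    w <- setNames(numeric(8), genes)
    w[names(profile)] <- profile
    want <- oracleRunningSum(unname(w), 8:1)
    got <- runningSumDeviation(rp, profile)
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
})

test_that("the fast deviation equals the exhaustive all-k scan on random configurations", {
    set.seed(123)
    for (i in 1:300) {
        N <- sample(4:12, 1)
        genes <- sprintf("g%02d", 1:N)
        vals <- sort(rnorm(N), decreasing = TRUE)
        m <- sample(seq_len(N - 1), 1)
        support <- sample(genes, m)
        w <- setNames(runif(m, 0.05, 1), support)
        rp <- structure(list(genes = genes, values = vals),
                        class = "RankedProfile")
        wFull <- setNames(numeric(N), genes)
        wFull[support] <- w
        expect_equal(as.numeric(runningSumDeviation(rp, w)),
                     oracleRunningSum(unname(wFull), vals),
                     tolerance = 1e-12)
    }
})

test_that("pre-iExpr is the up deviation minus the down deviation", {
    genes <- sprintf("g%02d", 1:12)
    expr <- setNames(12:1, genes)
    rp <- rankProfile(expr)
    up <- setNames(c(1, 0.8), genes[1:2])
    down <- setNames(c(0.9, 0.6), genes[11:12])
    pf <- new("WeightProfiles", lncrna = "L", up = up, down = down,
              upValid = TRUE, downValid = TRUE, universe = genes)
    wUp <- setNames(numeric(12), genes); wUp[names(up)] <- up
    wDn <- setNames(numeric(12), genes); wDn[names(down)] <- down
    want <- oracleRunningSum(unname(wUp), 12:1) -
        oracleRunningSum(unname(wDn), 12:1)
    expect_equal(preIExprScore(rp, pf), want, tolerance = 1e-12)
    # extreme concordance: up genes on top, down genes at the bottom
    upT <- setNames(rep(1, 3), genes[1:3])
    dnB <- setNames(rep(1, 3), genes[10:12])
    pf2 <- new("WeightProfiles", lncrna = "L", up = upT, down = dnB,
               upValid = TRUE, downValid = TRUE, universe = genes)
    expect_equal(preIExprScore(rp, pf2), 2.0)
    # single-profile case: invalid up contributes zero
    pf3 <- new("WeightProfiles", lncrna = "L", up = upT, down = dnB,
               upValid = FALSE, downValid = TRUE, universe = genes)
    expect_equal(preIExprScore(rp, pf3), -(-1.0))
    pf4 <- new("WeightProfiles", lncrna = "L", up = upT, down = dnB,
               upValid = FALSE, downValid = FALSE, universe = genes)
    expect_true(is.na(preIExprScore(rp, pf4)))
})

test_that("the permutation null is seeded, bounded and feeds normalisation", {
    fx <- smallProfileFixture()
    n1 <- permutationNull(fx$expr, fx$profiles, nPerm = 1000, seed = 11)
    n2 <- permutationNull(fx$expr, fx$profiles, nPerm = 1000, seed = 11)
    expect_identical(n1, n2)
    expect_true(all(n1 >= -2 & n1 <= 2))
    # the value-weighted running sum is sign-asymmetric under permutation
    # (mass concentrates near the top), so the null is summarised by its
    # sign-conditional means, which must bracket zero
    expect_gt(mean(n1[n1 > 0]), 0)
    expect_lt(mean(n1[n1 < 0]), 0)
    expect_gt(mean(n1 > 0), 0.2)
    expect_gt(mean(n1 < 0), 0.2)
    # equal-size symmetric profiles give a null symmetric about zero
    genes <- fx$genes
    pfSym <- new("WeightProfiles", lncrna = "S",
                 up = setNames(rep(0.7, 6), genes[1:6]),
                 down = setNames(rep(0.7, 6), genes[7:12]),
                 upValid = TRUE, downValid = TRUE, universe = genes)
    ns <- permutationNull(fx$expr, pfSym, nPerm = 2000, seed = 5)
    expect_lt(abs(mean(ns)), 3 * sd(ns) / sqrt(length(ns)))

    rec <- normalizeIExpr(2.0, c(0.5, 0.5, -0.25))
    expect_equal(rec$iexpr, 4.0)
    expect_equal(normalizeIExpr(0, n1)$iexpr, 0)
    expect_equal(normalizeIExpr(0, n1, "literal_mean")$iexpr, 0)
    # literal mode divides by the plain mean
    expect_equal(normalizeIExpr(0.3, c(0.1, 0.2), "literal_mean")$iexpr, 2)
    # sign-conditional with no negative nulls flags a negative score
    rec2 <- normalizeIExpr(-0.5, c(0.1, 0.2))
    expect_equal(rec2$iexpr, 0)
    expect_match(rec2$flag, "zero_null")
    expect_error(normalizeIExpr(1, numeric(0)), "empty")
})

test_that("matrix inference agrees with the per-cell composition of the unit operations", {
    fx <- smallProfileFixture()
    expr <- cbind(s1 = fx$expr, s2 = rev(fx$expr))
    rownames(expr) <- fx$genes
    ie <- inferExpression(expr, list(fx$profiles), nPerm = 150, seed = 4)
    for (s in 1:2) {
        rp <- rankProfile(expr[, s])
        pre <- preIExprScore(rp, fx$profiles)
        null <- permutationNull(expr[, s], fx$profiles, nPerm = 150,
                                seed = lncProg:::.cellSeed(4, 1, s))
        rec <- normalizeIExpr(pre, null)
        expect_equal(unname(preIexpr(ie)[1, s]), pre, tolerance = 1e-12)
        expect_equal(unname(iexpr(ie)[1, s]), rec$iexpr, tolerance = 1e-12)
    }
})

test_that("iExpr depends on a sample only through its within-sample ranking", {
    fx <- smallProfileFixture()
    set.seed(20)
    expr <- matrix(rnorm(50 * 6), 50, 6,
                   dimnames = list(fx$genes, paste0("s", 1:6)))
    ie1 <- inferExpression(expr, list(fx$profiles), nPerm = 100, seed = 9)
    # per-sample rank-preserving transforms: positive affine + monotone
    expr2 <- expr
    for (s in 1:6) expr2[, s] <- exp(expr[, s] * (0.5 + 0.2 * s)) + s
    ie2 <- inferExpression(expr2, list(fx$profiles), nPerm = 100, seed = 9)
    expect_identical(iexpr(ie1), iexpr(ie2))
    expect_identical(preIexpr(ie1), preIexpr(ie2))
})

test_that("profile genes missing from the array are dropped and coverage flagged", {
    fx <- smallProfileFixture()
    keep <- setdiff(fx$genes, names(upProfile(fx$profiles))[1:5])
    set.seed(3)
    expr <- matrix(rnorm(length(keep) * 4), length(keep), 4,
                   dimnames = list(keep, paste0("s", 1:4)))
    ie <- inferExpression(expr, list(fx$profiles), nPerm = 50, seed = 2)
    rd <- SummarizedExperiment::rowData(ie)
    expect_equal(rd$droppedGenes, 5)
    expect_false(rd$lowCoverage)
    # drop most of the support -> low coverage flag
    keep2 <- setdiff(fx$genes, c(names(upProfile(fx$profiles)),
                                 names(downProfile(fx$profiles))[1:4]))
    expr2 <- matrix(rnorm(length(keep2) * 2), length(keep2), 2,
                    dimnames = list(keep2, paste0("s", 1:2)))
    ie2 <- inferExpression(expr2, list(fx$profiles), nPerm = 50, seed = 2)
    expect_true(SummarizedExperiment::rowData(ie2)$lowCoverage)
})

test_that("iExpr recovers planted activity and flips under sign reversal", {
    cfg <- simConfig(nLncrna = 6, nCoding = 300, nSamplesRnaseq = 80,
                     regulonSizeMean = 30, nHazardous = 2, nProtective = 2,
                     seed = 14)
    ch <- simulateRegulatoryCohort(cfg)
    pfs <- trueWeightProfiles(ch$truth, rownames(ch$expr), minGenes = 15)
    ie <- inferExpression(ch$expr, pfs, nPerm = 100, seed = 14)
    act <- trueActivity(ch$truth)
    sp <- vapply(rownames(iexpr(ie)), function(l)
        cor(iexpr(ie)[l, ], act[l, ], method = "spearman"), numeric(1))
    expect_true(all(sp > 0.5))
    # negating every target effect flips the iExpr sign structure
    lncRows <- rownames(act)
    exprFlip <- ch$expr
    coding <- setdiff(rownames(exprFlip), lncRows)
    exprFlip[coding, ] <- -exprFlip[coding, ]
    ieF <- inferExpression(exprFlip, pfs, nPerm = 100, seed = 14)
    spF <- vapply(rownames(iexpr(ieF)), function(l)
        cor(iexpr(ieF)[l, ], act[l, ], method = "spearman"), numeric(1))
    expect_true(all(spF < 0))
})
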