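test_that("one-sided Fisher test matches the printed example and conventions", {
    res <- fisherExactOneSided(matrix(c(10, 5, 2, 20), 2, 2, byrow = TRUE))
    expect_equal(res$oddsRatio, 20)
    expect_equal(res$p, oracleFisherUpper(10, 5, 2, 20), tolerance = 1e-12)
    flat <- fisherExactOneSided(matrix(5, 2, 2))
    expect_equal(flat$oddsRatio, 1)
    expect_gt(flat$p, 0.5)
    deg <- fisherExactOneSided(matrix(c(4, 0, 3, 7), 2, 2, byrow = TRUE))
    expect_true(deg$degenerateOR)
    expect_true(is.infinite(deg$oddsRatio))
    expect_gt(deg$p, 0)
    expect_lte(deg$p, 1)
    expect_error(fisherExactOneSided(matrix(c(-1, 0, 1, 2), 2, 2)),
                 "non-negative")
})

test_that("classification schemes reproduce a literal re-application of the rules", {
    set.seed(91)
    n <- 100
    meta <- data.frame(lncrna = sprintf("L%03d", 1:n),
                       metaZ = rnorm(n, sd = 2),
                       stringsAsFactors = FALSE)
    meta$metaP <- 2 * pnorm(-abs(meta$metaZ))
    meta$fdrBH <- adjustPvalues(meta$metaP, "BH")
    # single printed examples
    one <- data.frame(lncrna = "L1", metaZ = 2.5, metaP = 1e-4,
                      fdrBH = 0.005)
    expect_equal(classifyPrognostic(one, "metabric_cna")$hazardous, "L1")
    one$metaZ <- -2.5
    expect_equal(classifyPrognostic(one, "metabric_cna")$protective, "L1")
    # literal transcription of each scheme over the 100-lncRNA fixture
    schemes <- list(
        precog_essentiality = with(meta, metaP <= 0.1),
        metabric_cna = with(meta, fdrBH <= 0.01),
        cross_dataset = with(meta, fdrBH < 0.05),
        tcga_cna_p = with(meta, metaP < 0.05),
        tcga_cna_fdr = with(meta, fdrBH <= 0.1))
    for (nm in names(schemes)) {
        got <- classifyPrognostic(meta, nm)
        pass <- schemes[[nm]]
        expect_setequal(got$hazardous, meta$lncrna[pass & meta$metaZ > 0])
        expect_setequal(got$protective, meta$lncrna[pass & meta$metaZ < 0])
        expect_length(intersect(got$hazardous, got$protective), 0)
    }
    # cross-dataset scheme: non-prognostic stratum is FDR > 0.1
    cd <- classifyPrognostic(meta, "cross_dataset")
    expect_setequal(cd$nonPrognostic, meta$lncrna[meta$fdrBH > 0.1])
    expect_error(classifyPrognostic(meta, "nope"), "unknown scheme")
})

test_that("Fisher p equals hypergeometric enumeration across small-margin tables", {
    tabs <- expand.grid(a = 0:8, b = 0:8, c = 0:8, d = 0:8)
    tabs <- tabs[rowSums(tabs) > 0, ]
    got <- apply(tabs, 1, function(r)
        fisherExactOneSided(matrix(r, 2, 2, byrow = TRUE))$p)
    want <- mapply(oracleFisherUpper, tabs$a, tabs$b, tabs$c, tabs$d)
    expect_equal(unname(got), unname(want), tolerance = 1e-11)
})

test_that("cross-dataset validation is maximal on self-comparison and null on noise", {
    set.seed(101)
    n <- 200
    meta <- data.frame(lncrna = sprintf("L%03d", 1:n),
                       metaZ = rnorm(n, sd = 2.5),
                       stringsAsFactors = FALSE)
    meta$metaP <- 2 * pnorm(-abs(meta$metaZ))
    meta$fdrBH <- adjustPvalues(meta$metaP, "BH")
    self <- crossDatasetValidation(meta, meta)
    expect_equal(self$pearsonR, 1.0)
    expect_gt(self$hazardous$oddsRatio, 1)
    expect_gt(self$protective$oddsRatio, 1)
    # independent screens: correlation within 3 SE of zero
    metaB <- meta
    set.seed(102)
    metaB$metaZ <- rnorm(n, sd = 2.5)
    metaB$metaP <- 2 * pnorm(-abs(metaB$metaZ))
    metaB$fdrBH <- adjustPvalues(metaB$metaP, "BH")
    ind <- crossDatasetValidation(meta, metaB)
    expect_lt(abs(ind$pearsonR), 3 / sqrt(n))
    expect_error(crossDatasetValidation(meta,
                                        data.frame(lncrna = "ZZZ",
                                                   metaZ = 1, fdrBH = 1)),
                 "shared")
})

test_that("concordant noisy screens validate in both directions", {
    set.seed(110)
    n <- 300
    trueZ <- rnorm(n, sd = 2.2)
    mk <- function(noise, seed) {
        set.seed(seed)
        z <- trueZ + rnorm(n, sd = noise)
        d <- data.frame(lncrna = sprintf("L%03d", 1:n), metaZ = z)
        d$metaP <- 2 * pnorm(-abs(z))
        d$fdrBH <- adjustPvalues(d$metaP, "BH")
        d
    }
    va <- crossDatasetValidation(mk(0.8, 1), mk(0.8, 2))
    expect_gt(va$pearsonR, 0.5)
    expect_gt(va$hazardous$oddsRatio, 1)
    expect_gt(va$protective$oddsRatio, 1)
})

test_that("essentiality enrichment rewards overlap and centres at one under the null", {
    universe <- sprintf("L%03d", 1:120)
    hazardous <- universe[1:25]
    protective <- universe[26:50]
    screen <- data.frame(gene = universe,
                         avg_phenotype_score = ifelse(universe %in% hazardous,
                                                      -0.5, 0.2),
                         p = 0.01, stringsAsFactors = FALSE)
    res <- essentialityEnrichment(hazardous, protective, screen)
    expect_setequal(res$essential, hazardous)
    expect_true(is.infinite(res$hazardous$oddsRatio))
    expect_lt(res$hazardous$p, 1e-6)
    expect_lt(res$protective$oddsRatio, 1)
    # p > 0.1 disqualifies essential calls
    screen2 <- screen; screen2$p <- 0.5
    expect_length(essentialityEnrichment(hazardous, protective,
                                         screen2)$essential, 0)
    # random essential set: odds ratios centre at 1
    set.seed(7)
    ors <- replicate(40, {
        scr <- screen
        scr$avg_phenotype_score <- sample(scr$avg_phenotype_score)
        r <- essentialityEnrichment(hazardous, protective, scr)$hazardous
        r$oddsRatio
    })
    lor <- log(ors[is.finite(ors) & ors > 0])
    expect_lt(abs(mean(lor)), 3 * sd(lor) / sqrt(length(lor)) + 0.25)
})

test_that("gene CNA signal is the unweighted mean over overlapping segments", {
    gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 250))
    segs <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(1, 200, 400),
                                                    c(199, 399, 500)))
    segs$signal <- c(0.4, 0.0, 9)
    expect_equal(geneCnaSignal(gene, segs), 0.2)
    within <- GenomicRanges::GRanges("chr1", IRanges::IRanges(210, 220))
    expect_equal(geneCnaSignal(within, segs), 0.0)
    one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
    one$signal <- -0.3
    expect_equal(geneCnaSignal(gene, one), -0.3)
    expect_warning(bad <- geneCnaSignal(
        GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10)), segs),
        "chromosome")
    expect_true(is.na(bad))
    # invariant to segment order and to equal-signal splits
    expect_equal(geneCnaSignal(gene, rev(segs)), 0.2)
    split2 <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(c(1, 100, 200, 400),
                                                      c(99, 199, 399, 500)))
    split2$signal <- c(0.4, 0.4, 0.0, 9)
    expect_equal(geneCnaSignal(gene, split2), 0.2)
    # straddling three segments in the synthetic genome vs literal script
    iv <- syntheticGeneIntervals(sprintf("L%02d", 1:10), nChrom = 2,
                                 geneLength = 30000, gap = 0)
    segs3 <- GenomicRanges::GRanges("chrS1",
                                    IRanges::IRanges(c(1, 10001, 20001),
                                                     c(10000, 20000, 60000)))
    segs3$signal <- c(0.1, -0.2, 0.7)
    want <- mean(segs3$signal)
    expect_equal(geneCnaSignal(iv["L01"], segs3), want)
})

test_that("per-patient CNA enrichment applies the minimum-cell rule and direction symmetry", {
    haz <- sprintf("H%02d", 1:12)
    pro <- sprintf("P%02d", 1:12)
    iv <- syntheticGeneIntervals(c(haz, pro), nChrom = 4)
    mkProfile <- function(ampGenes, delGenes) {
        segs <- iv  # one segment per gene for full control
        segs$signal <- 0
        segs$call <- 0L
        segs$call[names(segs) %in% ampGenes] <- 1L
        segs$call[names(segs) %in% delGenes] <- -1L
        segs
    }
    profiles <- list(
        pt1 = mkProfile(c(haz[1:7], pro[1:5]), pro[6:8]),  # concordant
        pt2 = mkProfile(c(haz[1:5], pro[1:5]), character()),
        pt3 = mkProfile(haz[1:2], character()))  # 4-count cell -> skipped
    amp <- patientCnaEnrichment(haz, pro, iv, profiles, "amplification")
    expect_equal(amp$tested, c(TRUE, TRUE, FALSE))
    expect_true(is.na(amp$p[3]))
    expect_true(is.na(amp$fdrBH[3]))
    expect_gt(amp$log2OR[1], 0)
    # literal re-computation of each table
    ivDf <- data.frame(gene = names(iv),
                       chrom = as.character(GenomicRanges::seqnames(iv)),
                       start = GenomicRanges::start(iv),
                       end = GenomicRanges::end(iv))
    for (i in seq_along(profiles)) {
        g <- profiles[[i]]
        segDf <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                            start = GenomicRanges::start(g),
                            end = GenomicRanges::end(g), call = g$call)
        tab <- oraclePatientCnaTable(haz, pro, ivDf, segDf, 1L)
        expect_equal(unlist(amp[i, c("a", "b", "c", "d")], use.names = FALSE),
                     as.vector(t(tab)))
        expect_equal(amp$tested[i], all(tab >= 5))
    }
    # swapping direction and the two sets yields identical tables
    del <- patientCnaEnrichment(pro, haz, iv, profiles, "deletion")
    ampSwap <- patientCnaEnrichment(haz, pro, iv, profiles, "deletion")
    expect_equal(unname(as.matrix(del[, c("a", "b")])),
                 unname(as.matrix(ampSwap[, c("c", "d")])))
    expect_error(patientCnaEnrichment(character(), pro, iv, profiles,
                                      "amplification"), "non-empty")
})

test_that("top-variance selection matches a naive sort and handles edge cases", {
    set.seed(120)
    m <- matrix(rnorm(1000 * 12), 1000, 12,
                dimnames = list(sprintf("L%04d", 1:1000), NULL))
    m[17, ] <- 0  # constant row ranks last
    top <- selectTopVariable(m, 100)
    v <- apply(m, 1, var)
    want <- rownames(m)[order(-v, rownames(m))][1:100]
    expect_identical(rownames(top), want)
    expect_false("L0017" %in% rownames(top))
    expect_identical(rownames(selectTopVariable(m, 1000)),
                     rownames(m)[order(-v, rownames(m))])
    expect_warning(all <- selectTopVariable(m[1:5, ], 10), "exceeds")
    expect_equal(nrow(all), 5)
})

test_that("row clustering matches brute-force complete linkage and splits planted blocks", {
    set.seed(130)
    m <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("r", 1:5), NULL))
    cl <- clusterRows(m)
    z <- t(scale(t(m)))
    want <- oracleCompleteLinkage(z)
    expect_equal(sort(cl$tree$height), sort(want$heights),
                 tolerance = 1e-12)
    cut2 <- cutree(cl$tree, 2)
    oracleSets <- lapply(want$twoCut, function(ix) sort(rownames(m)[ix]))
    gotSets <- lapply(split(names(cut2), cut2), sort)
    expect_setequal(vapply(gotSets, paste, character(1), collapse = ","),
                    vapply(oracleSets, paste, character(1), collapse = ","))
    # duplicate rows merge first at height zero
    m2 <- rbind(a = c(1, 2, 3, 9), b = c(1, 2, 3, 9), c = c(9, 1, 2, 0),
                d = c(0, 7, 1, 4))
    cl2 <- clusterRows(m2)
    expect_equal(min(cl2$tree$height), 0, tolerance = 1e-12)
    expect_setequal(rownames(m2)[cl2$tree$merge[1, ] * -1], c("a", "b"))
    # planted blocks with opposed sample patterns: first bipartition
    # separates them exactly
    pat <- c(rep(2, 3), rep(-2, 3))
    blocks <- rbind(
        matrix(rep(pat, each = 10), 10, 6) + matrix(rnorm(60, sd = 0.2), 10),
        matrix(rep(-pat, each = 10), 10, 6) + matrix(rnorm(60, sd = 0.2), 10))
    dimnames(blocks) <- list(sprintf("g%02d", 1:20), paste0("s", 1:6))
    cb <- cutree(clusterRows(blocks)$tree, 2)
    expect_length(unique(cb[1:10]), 1)
    expect_length(unique(cb[11:20]), 1)
    expect_true(cb[1] != cb[20])
    # permutation invariance up to relabelling
    perm <- sample(nrow(blocks))
    cp <- cutree(clusterRows(blocks[perm, ])$tree, 2)[rownames(blocks)]
    expect_identical(unname(cp == cp[1]), unname(cb == cb[1]))
    expect_warning(clusterRows(rbind(a = rep(1, 4), b = rnorm(4),
                                     c = rnorm(4))), "zero-variance")
})
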