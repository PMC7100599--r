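# Shared fixtures. The heavier cohorts are computed once per test run and
# memoised so that several test files can reuse them.

.fixtureCache <- new.env(parent = emptyenv())

memoise1 <- function(name, fn) {
    if (!exists(name, .fixtureCache)) assign(name, fn(), .fixtureCache)
    get(name, .fixtureCache)
}

# Standard synthetic cohort (the documented recovery configuration).
stdCohort <- function() memoise1("stdCohort", function() {
    simulateRegulatoryCohort(simConfig())
})

# Consensus network + profiles learned on the standard cohort.
stdRegulonRun <- function() memoise1("stdRegulonRun", function() {
    ch <- stdCohort()
    lnc <- rownames(trueActivity(ch$truth))
    net <- bootstrapConsensus(ch$expr, lnc, nBootstrap = 20L,
                              nNull = 1000L, seed = 1L)
    withReg <- intersect(lnc, unique(c(networkEdges(net)$regulator,
                                       networkEdges(net)$target)))
    regulons <- lapply(withReg, function(l) buildRegulon(net, ch$expr, l))
    names(regulons) <- withReg
    profiles <- lapply(regulons, makeWeightProfiles,
                       geneUniverse = rownames(ch$expr))
    profiles <- Filter(isInferable, profiles)
    list(network = net, regulons = regulons, profiles = profiles)
})

# iExpr of the standard cohort under the recovered profiles.
stdIExpr <- function() memoise1("stdIExpr", function() {
    inferExpression(stdCohort()$expr, stdRegulonRun()$profiles,
                    nPerm = 200L, seed = 1L)
})

# Small 50-gene universe with a mixed up/down profile for BASE unit tests.
smallProfileFixture <- function(seed = 11L) {
    set.seed(seed)
    genes <- sprintf("G%02d", 1:50)
    expr <- setNames(rnorm(50), genes)
    up <- setNames(runif(8, 0.3, 1), genes[1:8])
    up[1] <- 1
    down <- setNames(runif(6, 0.3, 0.99), genes[9:14])
    pf <- new("WeightProfiles", lncrna = "LNCX", up = up, down = down,
              upValid = TRUE, downValid = TRUE, universe = genes)
    list(expr = expr, profiles = pf, genes = genes)
}

# Tiny survival fixture with distinct event times (tie-free).
tinySurvFixture <- function() {
    data.frame(sample = paste0("p", 1:6),
               time = c(2, 3.5, 5, 7, 9, 11),
               event = c(1, 1, 1, 1, 1, 0),
               dataset = "DS01", stringsAsFactors = FALSE)
}
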