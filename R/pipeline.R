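# End-to-end synthetic pipeline: simulate, learn regulons, infer iExpr,
# screen survival, run the downstream enrichment analyses and write every
# stage's output to TSV.

#' Run the full pipeline on a synthetic cohort
#'
#' Exercises every stage end-to-end on generated data with known ground
#' truth: (1) simulate an RNA-seq-like training cohort with planted
#' regulons and prognostic effects; (2) learn the lncRNA regulon network by
#' bootstrap-consensus MI with DPI pruning and convert it to weight
#' profiles; (3) simulate a microarray-like compendium with survival and
#' infer lncRNA expression in it; (4) screen every lncRNA per dataset with
#' univariate Cox models and combine them by weighted Stouffer
#' meta-analysis; (5) classify hazardous/protective lncRNAs and test
#' copy-number and essentiality enrichment; (6) select top-variance
#' lncRNAs and cluster them. All outputs are written as TSV under
#' \code{outDir}; the run is bit-reproducible under a fixed config.
#'
#' @param config a \linkS4class{SimulationConfig}; its seed drives every
#'   stage.
#' @param outDir output directory (created if missing); \code{NULL} skips
#'   file output.
#' @param nBootstrap,miP,nNull network-learning settings (see
#'   \code{\link{bootstrapConsensus}}).
#' @param nPerm permutations per iExpr cell.
#' @param minGenes minimum profile size.
#' @param scheme classification scheme (see
#'   \code{\link{classifyPrognostic}}).
#' @param estimator MI estimator.
#' @return Invisibly, a list with every intermediate object: \code{truth},
#'   \code{network}, \code{regulons}, \code{profiles}, \code{compendium},
#'   \code{iexpr} (per dataset), \code{screens}, \code{meta},
#'   \code{classes}, \code{cna}, \code{essentiality}, \code{clustering}.
#' @export
runSyntheticPipeline <- function(config = simConfig(), outDir = NULL,
                                 nBootstrap = 20L, miP = 0.01,
                                 nNull = 1000L, nPerm = 200L,
                                 minGenes = 20L,
                                 scheme = "precog_essentiality",
                                 estimator = "adaptive_partition") {
    seed <- config@seed
    cohort <- simulateRegulatoryCohort(config)
    truth <- cohort$truth
    lnc <- rownames(truth@activity)
    pcg <- setdiff(rownames(cohort$expr), lnc)

    network <- bootstrapConsensus(cohort$expr, lnc, nBootstrap = nBootstrap,
                                  miP = miP, nNull = nNull,
                                  estimator = estimator, seed = seed)
    withReg <- intersect(lnc, unique(c(network@edges$regulator,
                                       network@edges$target)))
    regulons <- lapply(withReg, function(l)
        buildRegulon(network, cohort$expr, l))
    names(regulons) <- withReg
    universe <- rownames(cohort$expr)
    profiles <- lapply(regulons, makeWeightProfiles, geneUniverse = universe,
                       minGenes = minGenes)
    profiles <- Filter(isInferable, profiles)
    if (length(profiles) == 0L)
        stop("no inferable lncRNA profiles were recovered")

    compendium <- simulateMicroarrayCompendium(config, truth)
    iexprList <- lapply(seq_along(compendium), function(d)
        inferExpression(compendium[[d]]$expr, profiles, nPerm = nPerm,
                        seed = seed + d))
    screens <- do.call(rbind, lapply(seq_along(compendium), function(d)
        screenSurvival(iexprList[[d]], compendium[[d]]$survival)))
    meta <- metaAnalyze(screens)
    classes <- classifyPrognostic(meta, scheme)

    cna <- essentiality <- NULL
    if (length(classes$hazardous) && length(classes$protective)) {
        intervals <- syntheticGeneIntervals(lnc)
        segProfiles <- simulateCnaProfiles(config, truth, intervals)
        cna <- list(
            amplification = patientCnaEnrichment(
                classes$hazardous, classes$protective, intervals,
                segProfiles, "amplification"),
            deletion = patientCnaEnrichment(
                classes$hazardous, classes$protective, intervals,
                segProfiles, "deletion"))
        screen <- simulateEssentialityScreen(truth, seed = seed + 7L)
        essentiality <- essentialityEnrichment(
            classes$hazardous, classes$protective, screen)
    }

    k <- min(500L, nrow(iexpr(iexprList[[1L]])))
    top <- selectTopVariable(iexprList[[1L]], k)
    clustering <- if (nrow(top) >= 2L)
        tryCatch(clusterRows(top), error = function(e) NULL) else NULL

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeExpressionTsv(cohort$expr, file.path(outDir, "cohort_expr.tsv"))
        writeRegulonTsv(regulons, file.path(outDir, "regulons.tsv"))
        writeProfilesTsv(profiles, file.path(outDir, "profiles.tsv"))
        for (d in seq_along(compendium)) {
            writeExpressionTsv(compendium[[d]]$expr,
                               file.path(outDir,
                                         sprintf("dataset%02d_expr.tsv", d)))
            writeSurvivalTsv(compendium[[d]]$survival,
                             file.path(outDir,
                                       sprintf("dataset%02d_surv.tsv", d)))
            writeIExprTsv(iexprList[[d]],
                          file.path(outDir,
                                    sprintf("dataset%02d_iexpr.tsv", d)))
        }
        .writeTsv(screens, file.path(outDir, "cox_screens.tsv"))
        .writeTsv(meta, file.path(outDir, "meta_results.tsv"))
        if (!is.null(cna)) {
            .writeTsv(cna$amplification,
                      file.path(outDir, "cna_amplification.tsv"))
            .writeTsv(cna$deletion, file.path(outDir, "cna_deletion.tsv"))
        }
        if (!is.null(clustering))
            writeLines(clustering$order, file.path(outDir, "row_order.txt"))
    }
    invisible(list(truth = truth, network = network, regulons = regulons,
                   profiles = profiles, compendium = compendium,
                   iexpr = iexprList, screens = screens, meta = meta,
                   classes = classes, cna = cna,
                   essentiality = essentiality, clustering = clustering))
}
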