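# Regulon construction: bootstrap MI network consensus, signed weights,
# up/down weight profiles.

.checkExprMatrix <- function(expr) {
    if (is(expr, "SummarizedExperiment"))
        expr <- SummarizedExperiment::assay(expr)
    if (!is.matrix(expr) || !is.numeric(expr))
        stop("expression must be a numeric matrix (genes x samples)")
    if (is.null(rownames(expr)) || is.null(colnames(expr)))
        stop("expression matrix must carry gene and sample identifiers")
    if (anyDuplicated(rownames(expr)))
        stop("duplicate gene identifiers")
    if (anyDuplicated(colnames(expr)))
        stop("duplicate sample identifiers")
    if (!all(is.finite(expr)))
        stop("expression values must be finite")
    expr
}

#' Bootstrap-consensus mutual information network
#'
#' For each bootstrap the samples are resampled with replacement, MI is
#' estimated between every regulator and every other gene, edges below the
#' permutation-null threshold are dropped, and the data processing
#' inequality prunes indirect edges. Edges are then kept when their support
#' count is significant under a Poisson null with mean equal to the average
#' occurrences per distinct edge, Bonferroni-corrected at
#' \code{consensusP}; a plain support-fraction cutoff is available as an
#' alternative. With a single bootstrap the consensus step is skipped and
#' the bootstrap network is returned as-is.
#'
#' @param expr gene-by-sample numeric matrix with dimnames (or a
#'   \code{SummarizedExperiment}).
#' @param regulators character vector of regulator gene IDs, all present in
#'   \code{expr}.
#' @param nBootstrap number of bootstrap iterations (default 100).
#' @param miP MI significance level for the permutation-null threshold
#'   (default 0.01).
#' @param consensusP consensus significance level (Poisson mode).
#' @param estimator,bins MI estimator, see \code{\link{estimateMI}}.
#' @param dpiTolerance DPI tolerance, see \code{\link{applyDPI}}.
#' @param nNull null draws for the MI threshold.
#' @param consensusMode \code{"poisson"} (default) or \code{"fraction"}.
#' @param supportFraction minimum support fraction in \code{"fraction"} mode.
#' @param seed integer RNG seed.
#' @return An \linkS4class{MINetwork}; edge MI is the mean over supporting
#'   bootstraps.
#' @export
bootstrapConsensus <- function(expr, regulators, nBootstrap = 100L,
                               miP = 0.01, consensusP = 0.05,
                               estimator = c("adaptive_partition",
                                             "equifreq_bins"),
                               bins = 8L, dpiTolerance = 0, nNull = 1000L,
                               consensusMode = c("poisson", "fraction"),
                               supportFraction = 0.5, seed = 1L) {
    estimator <- match.arg(estimator)
    consensusMode <- match.arg(consensusMode)
    expr <- .checkExprMatrix(expr)
    if (!all(regulators %in% rownames(expr)))
        stop("all regulators must be present among the gene identifiers")
    n <- ncol(expr)
    if (n < 8L) stop("at least 8 samples are required")
    nBootstrap <- as.integer(nBootstrap)
    if (nBootstrap < 1L) stop("nBootstrap must be >= 1")
    est <- if (estimator == "adaptive_partition") 1L else 2L
    genes <- rownames(expr)
    regIdx <- match(regulators, genes)

    threshold <- miThreshold(n, miP, nNull, estimator, bins, seed = seed)
    set.seed(seed)
    pieces <- vector("list", nBootstrap)
    for (b in seq_len(nBootstrap)) {
        cols <- if (nBootstrap == 1L) seq_len(n)
                else sample.int(n, replace = TRUE)
        ranks <- .rank_rows_cpp(expr[, cols, drop = FALSE])
        mi <- .mi_all_pairs_cpp(ranks, regIdx, est, as.integer(bins))
        hits <- which(!is.na(mi) & mi > threshold, arr.ind = TRUE)
        if (nrow(hits) == 0L) next
        edf <- data.frame(regulator = regulators[hits[, 1L]],
                          target = genes[hits[, 2L]],
                          mi = mi[hits], support = 1L,
                          stringsAsFactors = FALSE)
        # deduplicate regulator-regulator pairs counted in both directions
        swap <- edf$target %in% regulators & edf$target < edf$regulator
        if (any(swap)) {
            tmp <- edf$regulator[swap]
            edf$regulator[swap] <- edf$target[swap]
            edf$target[swap] <- tmp
        }
        edf <- edf[!duplicated(paste(edf$regulator, edf$target, sep = "\r")), ]
        net <- applyDPI(MINetwork(edf, 1L), dpiTolerance)
        pieces[[b]] <- net@edges[, c("regulator", "target", "mi")]
    }
    all <- data.table::rbindlist(pieces)
    if (nrow(all) == 0L)
        return(MINetwork(data.frame(regulator = character(),
                                    target = character(), mi = numeric(),
                                    support = integer()), nBootstrap))
    regulator <- target <- NULL  # NSE guards
    cons <- all[, list(mi = mean(mi), support = .N),
                by = list(regulator, target)]
    if (nBootstrap > 1L) {
        if (consensusMode == "poisson") {
            # chance expectation per candidate pair (regulator x other gene,
            # regulator-regulator pairs counted once)
            nPairs <- length(regIdx) * (length(genes) - 1L) -
                choose(length(regIdx), 2L)
            mu <- nrow(all) / nPairs
            p <- stats::ppois(cons$support - 1L, mu, lower.tail = FALSE)
            keep <- p * nrow(cons) <= consensusP
        } else {
            keep <- cons$support / nBootstrap >= supportFraction
        }
        cons <- cons[keep]
    }
    MINetwork(as.data.frame(cons), nBootstrap)
}

#' Assemble a signed, max-normalised regulon
#'
#' Collects the network edges of one lncRNA, divides MI scores by the
#' regulon maximum so the largest weight is exactly 1, and signs each target
#' by the Pearson correlation between regulator and target expression.
#' Targets with a correlation of exactly zero fit neither profile and are
#' dropped.
#'
#' @param network an \linkS4class{MINetwork}.
#' @param expr the expression matrix the network was learned from.
#' @param lncrna regulator gene ID with at least one edge in the network.
#' @return A \linkS4class{Regulon}.
#' @export
buildRegulon <- function(network, expr, lncrna) {
    stopifnot(is(network, "MINetwork"))
    expr <- .checkExprMatrix(expr)
    e <- network@edges
    hit <- e$regulator == lncrna | e$target == lncrna
    if (!any(hit))
        stop("lncRNA '", lncrna, "' has no edges in the network")
    e <- e[hit, , drop = FALSE]
    targets <- ifelse(e$regulator == lncrna, e$target, e$regulator)
    if (!all(c(lncrna, targets) %in% rownames(expr)))
        stop("network genes missing from the expression matrix")
    r <- as.vector(stats::cor(expr[lncrna, ],
                              t(expr[targets, , drop = FALSE])))
    keep <- r != 0
    t <- data.frame(target = targets[keep], mi = e$mi[keep],
                    weight = e$mi[keep] / max(e$mi[keep]),
                    sign = ifelse(r[keep] > 0, 1, -1),
                    support = e$support[keep], stringsAsFactors = FALSE)
    new("Regulon", lncrna = lncrna,
        targets = t[order(t$target), c("target", "mi", "weight", "sign",
                                       "support")])
}

#' Split a regulon into up/down weight profiles
#'
#' Positively-signed weights populate the up profile and the magnitudes of
#' negatively-signed weights the down profile; everywhere else the profiles
#' are zero. A profile with fewer than \code{minGenes} members is flagged
#' invalid and contributes nothing downstream; when both profiles are
#' invalid the lncRNA is non-inferable.
#'
#' @param regulon a \linkS4class{Regulon}.
#' @param geneUniverse character vector containing every regulon target.
#' @param minGenes minimum profile size (default 20).
#' @return A \linkS4class{WeightProfiles}.
#' @export
makeWeightProfiles <- function(regulon, geneUniverse, minGenes = 20L) {
    stopifnot(is(regulon, "Regulon"))
    t <- regulon@targets
    if (!all(t$target %in% geneUniverse))
        stop("regulon targets outside the gene universe: ",
             paste(utils::head(setdiff(t$target, geneUniverse), 3L),
                   collapse = ", "))
    up <- stats::setNames(t$weight[t$sign > 0], t$target[t$sign > 0])
    down <- stats::setNames(t$weight[t$sign < 0], t$target[t$sign < 0])
    new("WeightProfiles", lncrna = regulon@lncrna, up = up, down = down,
        upValid = length(up) >= minGenes, downValid = length(down) >= minGenes,
        universe = as.character(geneUniverse))
}
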