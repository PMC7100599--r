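# Rank-based weighted running-sum inference of lncRNA expression (iExpr).

#' Rank a sample's expression profile
#'
#' Sorts one sample's gene expression from highest to lowest; ties are
#' broken deterministically by lexicographic gene ID.
#'
#' @param expr named numeric vector of one sample's expression.
#' @return A list with class \code{RankedProfile}: \code{genes} (gene IDs in
#'   descending-expression order) and \code{values} (expression in that
#'   order).
#' @export
rankProfile <- function(expr) {
    if (is.null(names(expr)) || anyDuplicated(names(expr)))
        stop("expression vector must carry unique gene names")
    if (!all(is.finite(expr))) stop("expression values must be finite")
    ord <- order(-expr, names(expr))
    structure(list(genes = names(expr)[ord], values = unname(expr[ord])),
              class = "RankedProfile")
}

.profilePositions <- function(ranked, profile) {
    pos <- match(names(profile), ranked$genes)
    if (anyNA(pos))
        stop("profile genes missing from the ranked universe: ",
             paste(utils::head(names(profile)[is.na(pos)], 3L),
                   collapse = ", "))
    pos
}

#' Signed maximum running-sum deviation
#'
#' Walks down a ranked expression profile accumulating a foreground
#' function F(k) (the cumulative share of weight times |expression| over the
#' profile genes) and a background function B(k) (the cumulative share of
#' the zero-weight genes), and returns F(k*) - B(k*) at the first rank k*
#' maximising |F - B|. Positive values mean the weighted genes concentrate
#' at the top of the ranking; the result always lies in [-1, 1].
#'
#' @param ranked a \code{RankedProfile} from \code{\link{rankProfile}}.
#' @param profile named non-negative weight vector (the nonzero entries of
#'   an up or down profile); all genes must be present in \code{ranked}.
#' @return The signed maximum deviation. An empty or all-zero profile
#'   returns 0 with attribute \code{degenerate = TRUE}; a profile covering
#'   the whole universe has no background and is an error.
#' @export
runningSumDeviation <- function(ranked, profile) {
    stopifnot(inherits(ranked, "RankedProfile"))
    profile <- profile[profile != 0]
    N <- length(ranked$genes)
    if (length(profile) == 0L)
        return(structure(0, degenerate = TRUE))
    if (length(profile) >= N)
        stop("profile support covers the whole universe; background undefined")
    if (any(profile < 0)) stop("profile weights must be non-negative")
    pos <- .profilePositions(ranked, profile)
    wabs <- unname(profile) * abs(ranked$values[pos])
    d <- .running_sum_dev_cpp(as.integer(pos), wabs, N)
    structure(as.numeric(d), degenerate = isTRUE(attr(d, "degenerate")))
}

#' Raw pre-iExpr score of one lncRNA in one sample
#'
#' The maximum deviation of the down profile is subtracted from the maximum
#' deviation of the up profile; an invalid profile contributes 0. High
#' values mean positively associated genes sit at the top of the sample's
#' ranking while negatively associated genes sit at the bottom.
#'
#' @param ranked a \code{RankedProfile}.
#' @param profiles a \linkS4class{WeightProfiles}.
#' @param useRankScores replace the expression values by their descending
#'   rank scores (N down to 1) before computing the deviations (default
#'   TRUE, matching \code{\link{inferExpression}}); FALSE uses the raw
#'   values.
#' @return The signed score in [-2, 2], or \code{NA} when both profiles are
#'   invalid (non-inferable lncRNA).
#' @export
preIExprScore <- function(ranked, profiles, useRankScores = TRUE) {
    stopifnot(is(profiles, "WeightProfiles"))
    if (!isInferable(profiles)) return(NA_real_)
    if (useRankScores) {
        N <- length(ranked$genes)
        ranked <- structure(list(genes = ranked$genes,
                                 values = as.numeric(N:1)),
                            class = "RankedProfile")
    }
    dUp <- if (profiles@upValid)
        runningSumDeviation(ranked, profiles@up) else 0
    dDown <- if (profiles@downValid)
        runningSumDeviation(ranked, profiles@down) else 0
    as.numeric(dUp) - as.numeric(dDown)
}

# Deterministic per-cell seed derivation shared by inferExpression and the
# standalone permutation-null generator (kept below 2^31).
.cellSeed <- function(seed, l, s) {
    (as.numeric(seed) * 1000003 + as.numeric(l) * 10007 +
         as.numeric(s)) %% 2147483647
}

#' Permutation null of the pre-iExpr score
#'
#' Repeatedly permutes the gene-to-expression assignment of one sample
#' uniformly at random and recomputes the pre-iExpr score, yielding the null
#' distribution used to normalise the observed score.
#'
#' @param expr named numeric vector of one sample's expression.
#' @param profiles a \linkS4class{WeightProfiles}.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @param useRankScores as in \code{\link{preIExprScore}}.
#' @return Numeric vector of \code{nPerm} null pre-iExpr values.
#' @export
permutationNull <- function(expr, profiles, nPerm = 1000L, seed = 1L,
                            useRankScores = TRUE) {
    stopifnot(is(profiles, "WeightProfiles"))
    if (nPerm < 1L) stop("nPerm must be >= 1")
    ranked <- rankProfile(expr)
    N <- length(ranked$genes)
    vals <- if (useRankScores) as.numeric(N:1) else abs(ranked$values)
    up <- if (profiles@upValid) profiles@up else numeric()
    down <- if (profiles@downValid) profiles@down else numeric()
    if (length(up) + length(down) == 0L)
        stop("both profiles invalid: lncRNA is non-inferable")
    # support positions are re-drawn under the permutation; only the counts,
    # the weights and the value ladder matter
    .perm_null_cpp(vals, unname(up), unname(down),
                   as.integer(nPerm), as.numeric(seed))
}

#' Normalise a pre-iExpr score against its permutation null
#'
#' In the default \code{sign_conditional} mode a non-negative score is
#' divided by the mean of the positive null values and a negative score by
#' the magnitude of the mean of the negative null values, preserving the
#' sign of the raw score. \code{literal_mean} divides by the plain null mean
#' instead; that denominator is near zero and sign-mixed, so the default is
#' the stable choice. A zero or unavailable denominator yields an iExpr of 0
#' with a warning flag.
#'
#' @param pre observed pre-iExpr score.
#' @param nullValues numeric vector of null pre-iExpr values.
#' @param mode \code{"sign_conditional"} (default) or \code{"literal_mean"}.
#' @return A one-row data.frame: \code{preIexpr}, \code{nullMeanPos},
#'   \code{nullMeanNeg}, \code{iexpr}, \code{nPerm}, \code{flag}.
#' @export
normalizeIExpr <- function(pre, nullValues,
                           mode = c("sign_conditional", "literal_mean")) {
    mode <- match.arg(mode)
    if (length(nullValues) == 0L) stop("empty null distribution")
    posMean <- if (any(nullValues > 0)) mean(nullValues[nullValues > 0])
               else NA_real_
    negMean <- if (any(nullValues < 0)) mean(nullValues[nullValues < 0])
               else NA_real_
    flag <- ""
    if (is.na(pre)) {
        ie <- NA_real_
        flag <- "non_inferable"
    } else if (mode == "sign_conditional") {
        denom <- if (pre >= 0) posMean else abs(negMean)
        if (is.na(denom) || denom == 0) {
            ie <- 0
            flag <- "zero_null_denominator"
        } else ie <- pre / denom
    } else {
        denom <- mean(nullValues)
        if (denom == 0) {
            ie <- 0
            flag <- "zero_null_denominator"
        } else ie <- pre / denom
    }
    data.frame(preIexpr = pre, nullMeanPos = posMean, nullMeanNeg = negMean,
               iexpr = ie, nPerm = length(nullValues), flag = flag,
               stringsAsFactors = FALSE)
}

#' Infer lncRNA expression across a whole expression matrix
#'
#' Applies the running-sum statistic with a permutation null to every
#' (inferable lncRNA, sample) pair. Each sample enters through its
#' within-sample ranking only: the statistic runs on the descending rank
#' scores (N down to 1), so any rank-preserving per-sample transform of the
#' input leaves the result bit-identical. Profile genes absent from the
#' array are dropped without renormalising the remaining weights (the
#' max-weight anchor is retained); a lncRNA whose profile coverage falls
#' below \code{minCoverage} is flagged low-coverage.
#'
#' @param expr gene-by-sample numeric matrix (or
#'   \code{SummarizedExperiment}); typically coding genes only.
#' @param profiles a list of \linkS4class{WeightProfiles}.
#' @param nPerm permutations per cell (default 1000).
#' @param seed integer RNG seed.
#' @param mode normalisation mode, see \code{\link{normalizeIExpr}}.
#' @param minCoverage minimum fraction of profile genes present on the
#'   array (default 0.5).
#' @return An \linkS4class{IExprMatrix} with one row per inferable lncRNA.
#' @export
inferExpression <- function(expr, profiles, nPerm = 1000L, seed = 1L,
                            mode = c("sign_conditional", "literal_mean"),
                            minCoverage = 0.5) {
    mode <- match.arg(mode)
    expr <- .checkExprMatrix(expr)
    if (is(profiles, "WeightProfiles")) profiles <- list(profiles)
    genes <- rownames(expr)
    N <- length(genes)
    S <- ncol(expr)

    info <- lapply(profiles, function(pf) {
        stopifnot(is(pf, "WeightProfiles"))
        up <- if (pf@upValid) pf@up else numeric()
        down <- if (pf@downValid) pf@down else numeric()
        support <- length(up) + length(down)
        up <- up[names(up) %in% genes]
        down <- down[names(down) %in% genes]
        present <- length(up) + length(down)
        list(lncrna = pf@lncrna,
             inferable = isInferable(pf) && present > 0L,
             coverage = if (support > 0L) present / support else 0,
             dropped = support - present,
             upIdx = match(names(up), genes), upW = unname(up),
             downIdx = match(names(down), genes), downW = unname(down))
    })
    keep <- vapply(info, `[[`, logical(1), "inferable")
    if (!any(keep)) stop("no inferable lncRNA profiles")
    info <- info[keep]
    L <- length(info)
    lnc <- vapply(info, `[[`, character(1), "lncrna")
    if (anyDuplicated(lnc)) stop("duplicate lncRNA profiles")

    valsAbs <- matrix(rep(as.numeric(N:1), S), N, S)
    rankPos <- matrix(0L, N, S)
    for (s in seq_len(S)) {
        ord <- order(-expr[, s], genes)
        rankPos[ord, s] <- seq_len(N)
    }
    cellSeeds <- outer(seq_len(L), seq_len(S),
                       function(l, s) .cellSeed(seed, l, s))
    plist <- lapply(info, function(x)
        list(upIdx = as.integer(x$upIdx), upW = x$upW,
             downIdx = as.integer(x$downIdx), downW = x$downW))
    raw <- .infer_iexpr_cpp(rankPos, valsAbs, plist, as.integer(nPerm),
                            cellSeeds)
    pre <- raw$pre
    ie <- matrix(0, L, S)
    flagged <- matrix(FALSE, L, S)
    if (mode == "sign_conditional") {
        denom <- ifelse(pre >= 0, raw$nullPosMean, abs(raw$nullNegMean))
        bad <- is.na(denom) | denom == 0
        ie <- ifelse(bad, 0, pre / denom)
        flagged <- bad
    } else {
        bad <- raw$nullMean == 0
        ie <- ifelse(bad, 0, pre / raw$nullMean)
        flagged <- bad
    }
    dimnames(pre) <- dimnames(ie) <- list(lnc, colnames(expr))
    rd <- S4Vectors::DataFrame(
        lncrna = lnc,
        nUp = vapply(info, function(x) length(x$upIdx), integer(1)),
        nDown = vapply(info, function(x) length(x$downIdx), integer(1)),
        coverage = vapply(info, `[[`, numeric(1), "coverage"),
        droppedGenes = vapply(info, `[[`, numeric(1), "dropped"),
        lowCoverage = vapply(info, `[[`, numeric(1), "coverage") <
            minCoverage)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(iexpr = ie, preIexpr = pre),
        rowData = rd,
        metadata = list(nPerm = as.integer(nPerm), seed = seed, mode = mode,
                        flaggedCells = sum(flagged)))
    new("IExprMatrix", se)
}
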