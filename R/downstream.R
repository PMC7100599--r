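# Downstream analyses: prognostic classification, enrichment tests,
# copy-number mapping, variance selection and clustering.

#' One-sided Fisher's exact test for enrichment
#'
#' For the 2x2 table \code{[[a, b], [c, d]]} returns the sample odds ratio
#' \code{(a*d)/(b*c)} and the one-sided enrichment p-value, the upper tail
#' of the hypergeometric distribution of the top-left cell at fixed
#' margins. A zero in \code{b} or \code{c} makes the odds ratio infinite;
#' the p-value remains defined.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List: \code{oddsRatio}, \code{p}, \code{log2OR},
#'   \code{degenerateOR} (TRUE when b or c is zero).
#' @export
fisherExactOneSided <- function(table) {
    table <- as.matrix(table)
    if (!all(dim(table) == c(2L, 2L)))
        stop("a 2x2 table is required")
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be non-negative integers")
    a <- table[1L, 1L]; b <- table[1L, 2L]
    c <- table[2L, 1L]; d <- table[2L, 2L]
    orv <- (a * d) / (b * c)  # Inf or NaN when b*c == 0
    p <- stats::phyper(a - 1L, a + b, c + d, a + c, lower.tail = FALSE)
    list(oddsRatio = orv, p = p, log2OR = log2(orv),
         degenerateOR = (b == 0 || c == 0))
}

# Registered threshold schemes: z-sign split plus a p-or-FDR cutoff, with
# the scheme-specific rule for the non-prognostic stratum.
.schemes <- list(
    precog_essentiality = list(stat = "metaP", cutoff = 0.1,
                               strict = FALSE),
    metabric_cna = list(stat = "fdrBH", cutoff = 0.01, strict = FALSE),
    cross_dataset = list(stat = "fdrBH", cutoff = 0.05, strict = TRUE,
                         nonCutoff = 0.1),
    tcga_cna_p = list(stat = "metaP", cutoff = 0.05, strict = TRUE),
    tcga_cna_fdr = list(stat = "fdrBH", cutoff = 0.1, strict = FALSE))

#' Classify lncRNAs as hazardous, protective or non-prognostic
#'
#' Applies one of the registered threshold schemes to a meta-analysis
#' result: hazardous lncRNAs have positive (meta) z passing the cutoff,
#' protective lncRNAs negative z passing the cutoff. The
#' \code{cross_dataset} scheme additionally defines the non-prognostic
#' stratum as FDR > 0.1, leaving the intermediate lncRNAs unassigned.
#'
#' Registered schemes: \code{precog_essentiality} (p <= 0.1),
#' \code{metabric_cna} (FDR <= 0.01), \code{cross_dataset} (FDR < 0.05
#' prognostic, FDR > 0.1 non-prognostic), \code{tcga_cna_p} (p < 0.05),
#' \code{tcga_cna_fdr} (FDR <= 0.1). A custom scheme is a list with
#' \code{stat} ("metaP" or "fdrBH"), \code{cutoff} and \code{strict}
#' (TRUE for strict inequality).
#'
#' @param meta data.frame from \code{\link{metaAnalyze}} (needs
#'   \code{lncrna}, a z column, \code{metaP}, \code{fdrBH}).
#' @param scheme scheme name or custom scheme list.
#' @param zColumn which z column to use (default \code{"metaZ"}).
#' @return List of character vectors: \code{hazardous}, \code{protective},
#'   \code{nonPrognostic}.
#' @export
classifyPrognostic <- function(meta, scheme = "precog_essentiality",
                               zColumn = "metaZ") {
    if (is.character(scheme)) {
        if (!scheme %in% names(.schemes))
            stop("unknown scheme '", scheme, "'; registered: ",
                 paste(names(.schemes), collapse = ", "))
        scheme <- .schemes[[scheme]]
    }
    stopifnot(all(c("stat", "cutoff") %in% names(scheme)),
              zColumn %in% colnames(meta))
    stat <- meta[[scheme$stat]]
    z <- meta[[zColumn]]
    pass <- if (isTRUE(scheme$strict)) stat < scheme$cutoff
            else stat <= scheme$cutoff
    pass <- pass & is.finite(z)
    nonCut <- if (!is.null(scheme$nonCutoff)) stat > scheme$nonCutoff
              else !pass
    list(hazardous = meta$lncrna[pass & z > 0],
         protective = meta$lncrna[pass & z < 0],
         nonPrognostic = meta$lncrna[nonCut & !pass])
}

#' Cross-dataset validation of prognostic calls
#'
#' Compares two screens over a shared lncRNA universe (e.g. actual
#' expression in one cohort vs inferred expression in another): reports the
#' Pearson correlation between the two z-score vectors, and per direction
#' (hazardous HR > 1, protective HR < 1) a one-sided Fisher enrichment of
#' prognostic lncRNAs (FDR < 0.05) of one screen in the prognostic set of
#' the other, with non-prognostic strata at FDR > 0.1 and intermediate
#' lncRNAs excluded.
#'
#' @param metaA,metaB data.frames with columns \code{lncrna}, a z column
#'   and \code{fdrBH}.
#' @param zColumn which z column to correlate and sign on.
#' @return List: \code{pearsonR}, \code{nShared}, \code{hazardous} and
#'   \code{protective} (each a \code{\link{fisherExactOneSided}} result
#'   with its table).
#' @export
crossDatasetValidation <- function(metaA, metaB, zColumn = "metaZ") {
    shared <- intersect(metaA$lncrna, metaB$lncrna)
    if (length(shared) == 0L) stop("no shared lncRNAs between the screens")
    a <- metaA[match(shared, metaA$lncrna), ]
    b <- metaB[match(shared, metaB$lncrna), ]
    za <- a[[zColumn]]; zb <- b[[zColumn]]
    ok <- is.finite(za) & is.finite(zb)
    r <- stats::cor(za[ok], zb[ok])
    direction <- function(sgn) {
        selA <- a$fdrBH < 0.05 & sign(za) == sgn
        selB <- b$fdrBH < 0.05 & sign(zb) == sgn
        nonA <- a$fdrBH > 0.1
        nonB <- b$fdrBH > 0.1
        use <- ok & (selA | nonA) & (selB | nonB)
        tab <- matrix(c(sum(use & selA & selB), sum(use & selA & nonB),
                        sum(use & nonA & selB), sum(use & nonA & nonB)),
                      2L, 2L, byrow = TRUE)
        res <- fisherExactOneSided(tab)
        res$table <- tab
        res
    }
    list(pearsonR = r, nShared = sum(ok),
         hazardous = direction(1), protective = direction(-1))
}

#' Enrichment of prognostic lncRNAs in an essentiality screen
#'
#' Calls a lncRNA essential when its average phenotype score is below zero
#' with screen p <= 0.1, then tests the one-sided enrichment of the
#' hazardous (and, separately, protective) set among essential lncRNAs over
#' the shared universe.
#'
#' @param hazardous,protective character vectors of prognostic lncRNA IDs.
#' @param screen data.frame with columns \code{gene},
#'   \code{avg_phenotype_score}, \code{p}.
#' @param universe optional explicit lncRNA universe (default: screen
#'   genes).
#' @return List with \code{hazardous} and \code{protective} enrichment
#'   results (table, odds ratio, one-sided p) and \code{essential}, the
#'   essential gene set.
#' @export
essentialityEnrichment <- function(hazardous, protective, screen,
                                   universe = NULL) {
    if (is.null(universe)) universe <- screen$gene
    if (length(intersect(universe, screen$gene)) == 0L)
        stop("no overlap between screen genes and the lncRNA universe")
    essential <- screen$gene[screen$avg_phenotype_score < 0 &
                                 screen$p <= 0.1]
    oneSet <- function(set) {
        inSet <- universe %in% set
        isEss <- universe %in% essential
        tab <- matrix(c(sum(inSet & isEss), sum(inSet & !isEss),
                        sum(!inSet & isEss), sum(!inSet & !isEss)),
                      2L, 2L, byrow = TRUE)
        res <- fisherExactOneSided(tab)
        res$table <- tab
        res
    }
    list(hazardous = oneSet(hazardous), protective = oneSet(protective),
         essential = essential)
}

#' Copy-number signal of a gene in one patient
#'
#' The unweighted mean of the copy-number signal over every segment with
#' any overlap of the gene interval. Returns \code{NA} when no segment
#' overlaps or the chromosome is absent from the profile.
#'
#' @param interval single-range \link[GenomicRanges]{GRanges} of the gene.
#' @param profile \link[GenomicRanges]{GRanges} of the patient's segments
#'   with a \code{signal} metadata column.
#' @return Mean signal, or \code{NA_real_} with a warning for an unknown
#'   chromosome.
#' @export
geneCnaSignal <- function(interval, profile) {
    stopifnot(is(interval, "GRanges"), length(interval) == 1L,
              is(profile, "GRanges"))
    if (!as.character(GenomicRanges::seqnames(interval)) %in%
        as.character(GenomicRanges::seqnames(profile))) {
        warning("chromosome absent from segment profile")
        return(NA_real_)
    }
    hits <- GenomicRanges::findOverlaps(interval, profile)
    if (length(hits) == 0L) return(NA_real_)
    mean(profile$signal[S4Vectors::subjectHits(hits)])
}

#' Per-patient enrichment of prognostic lncRNAs in CNA segments
#'
#' For each patient, builds the 2x2 table of {hazardous, protective}
#' lncRNAs by {overlapping a segment with the direction's call, not}. A
#' lncRNA counts as altered when any overlapping segment carries the call.
#' The test runs only when every cell has at least \code{minCell} counts;
#' the one-sided p targets the concordant class (hazardous in
#' amplifications, protective in deletions), and BH adjustment spans the
#' tested patients of the direction.
#'
#' @param hazardous,protective character vectors of prognostic lncRNA IDs.
#' @param intervals \link[GenomicRanges]{GRanges} named by gene covering
#'   every prognostic lncRNA.
#' @param profiles named list of per-patient segment
#'   \link[GenomicRanges]{GRanges} with a \code{call} column.
#' @param direction \code{"amplification"} (call +1) or \code{"deletion"}
#'   (call -1).
#' @param minCell minimum count per cell for the test to run (default 5).
#' @return data.frame with one row per patient: counts, \code{tested},
#'   \code{oddsRatio}, \code{log2OR}, \code{p}, \code{fdrBH} (NA for
#'   untested patients).
#' @export
patientCnaEnrichment <- function(hazardous, protective, intervals, profiles,
                                 direction = c("amplification", "deletion"),
                                 minCell = 5L) {
    direction <- match.arg(direction)
    if (length(hazardous) == 0L || length(protective) == 0L)
        stop("both prognostic sets must be non-empty")
    prog <- c(hazardous, protective)
    if (!all(prog %in% names(intervals)))
        stop("every prognostic lncRNA needs an interval")
    callWanted <- if (direction == "amplification") 1L else -1L
    gi <- intervals[prog]
    isHaz <- prog %in% hazardous
    rows <- lapply(names(profiles), function(p) {
        seg <- profiles[[p]]
        segSel <- seg[seg$call == callWanted]
        altered <- rep(FALSE, length(prog))
        if (length(segSel)) {
            hits <- GenomicRanges::findOverlaps(gi, segSel)
            altered[unique(S4Vectors::queryHits(hits))] <- TRUE
        }
        # concordant class in the first row
        first <- if (direction == "amplification") isHaz else !isHaz
        tab <- matrix(c(sum(first & altered), sum(first & !altered),
                        sum(!first & altered), sum(!first & !altered)),
                      2L, 2L, byrow = TRUE)
        tested <- all(tab >= minCell)
        res <- fisherExactOneSided(tab)
        data.frame(patient = p, a = tab[1L, 1L], b = tab[1L, 2L],
                   c = tab[2L, 1L], d = tab[2L, 2L], tested = tested,
                   oddsRatio = res$oddsRatio, log2OR = res$log2OR,
                   p = ifelse(tested, res$p, NA_real_),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdrBH <- NA_real_
    if (any(out$tested))
        out$fdrBH[out$tested] <- adjustPvalues(out$p[out$tested], "BH")
    rownames(out) <- NULL
    out
}

#' Select the most variable rows of an inferred-expression matrix
#'
#' Ranks rows by sample variance (ties broken by gene ID) and keeps the top
#' \code{k}.
#'
#' @param mat numeric matrix with rownames (or \linkS4class{IExprMatrix}).
#' @param k number of rows to keep (default 500); if larger than the row
#'   count, all rows are returned with a warning.
#' @return The reduced matrix, rows in decreasing-variance order.
#' @export
selectTopVariable <- function(mat, k = 500L) {
    if (is(mat, "IExprMatrix")) mat <- iexpr(mat)
    v <- apply(mat, 1L, stats::var)
    if (k > nrow(mat)) {
        warning("k exceeds the number of rows; returning all rows")
        k <- nrow(mat)
    }
    ord <- order(-v, rownames(mat))
    mat[ord[seq_len(k)], , drop = FALSE]
}

#' Hierarchical clustering of expression rows
#'
#' Rows are z-transformed across samples (zero-variance rows are excluded
#' with a warning), then clustered agglomeratively with Euclidean distance
#' and complete linkage.
#'
#' @param mat numeric matrix with rownames.
#' @param linkage linkage criterion (default \code{"complete"}).
#' @param metric distance metric (default \code{"euclidean"}).
#' @return List: \code{tree} (an \code{\link[stats]{hclust}} object) and
#'   \code{order} (row labels in dendrogram order).
#' @export
clusterRows <- function(mat, linkage = "complete", metric = "euclidean") {
    if (is(mat, "IExprMatrix")) mat <- iexpr(mat)
    if (nrow(mat) < 2L) stop("at least 2 rows are required")
    sds <- apply(mat, 1L, stats::sd)
    if (any(sds == 0)) {
        warning("excluding ", sum(sds == 0), " zero-variance row(s)")
        mat <- mat[sds > 0, , drop = FALSE]
        if (nrow(mat) < 2L) stop("fewer than 2 non-constant rows")
    }
    z <- t(scale(t(mat)))
    tree <- stats::hclust(stats::dist(z, method = metric), method = linkage)
    list(tree = tree, order = rownames(z)[tree$order])
}
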