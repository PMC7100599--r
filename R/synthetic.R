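# Synthetic cohort generators with planted ground truth.
#
# Latent lncRNA activity drives both target-gene expression and the hazard
# of death, mirroring the premise that a regulator's signal is carried by
# its regulon even when the regulator itself is unmeasured.

.lncIds <- function(n) sprintf("LNC%04d", seq_len(n))
.pcgIds <- function(n) sprintf("PCG%05d", seq_len(n))

#' Simulate an RNA-seq-like cohort with planted regulons
#'
#' Draws latent lncRNA activities, plants a signed weighted regulon for
#' every lncRNA, and emits a gene-by-sample expression matrix containing
#' both lncRNA rows (activity plus measurement noise) and coding rows
#' (signed weighted activity scaled by \code{signalStrength}, plus an
#' independent unit-variance Gaussian component, plus measurement noise).
#' Planted regulon weights are drawn from Uniform(0.5, 1), keeping every
#' target at a moderate-to-strong association. Hazard labels (hazardous
#' with +betaMagnitude, protective with -betaMagnitude) are assigned to the
#' first planted lncRNAs.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return List: \code{expr} (gene-by-sample matrix) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @export
simulateRegulatoryCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    nL <- config@nLncrna; nC <- config@nCoding; nS <- config@nSamplesRnaseq
    lnc <- .lncIds(nL); pcg <- .pcgIds(nC)
    samples <- sprintf("S%04d", seq_len(nS))

    activity <- matrix(stats::rnorm(nL * nS), nL, nS,
                       dimnames = list(lnc, samples))

    sizes <- pmax(1L, pmin(nC, stats::rpois(nL, config@regulonSizeMean)))
    reg <- do.call(rbind, lapply(seq_len(nL), function(l) {
        tg <- sample(pcg, sizes[l])
        data.frame(lncrna = lnc[l], target = tg,
                   sign = ifelse(stats::runif(sizes[l]) <
                                     config@fracNegativeEdges, -1, 1),
                   weight = stats::runif(sizes[l], 0.5, 1),
                   stringsAsFactors = FALSE)
    }))

    labels <- rep("null", nL)
    beta <- rep(0, nL)
    if (config@nHazardous > 0) {
        labels[seq_len(config@nHazardous)] <- "hazardous"
        beta[seq_len(config@nHazardous)] <- config@betaMagnitude
    }
    if (config@nProtective > 0) {
        idx <- config@nHazardous + seq_len(config@nProtective)
        labels[idx] <- "protective"
        beta[idx] <- -config@betaMagnitude
    }
    truth <- new("GroundTruth", activity = activity, regulons = reg,
                 prognosticLabels = data.frame(lncrna = lnc, label = labels,
                                               beta = beta,
                                               stringsAsFactors = FALSE),
                 essentialSet = lnc[labels == "hazardous"])

    expr <- .exprFromActivity(activity, reg, pcg, config)
    expr <- rbind(activity + matrix(stats::rnorm(nL * nS,
                                                 sd = config@noiseSd),
                                    nL, nS), expr)
    rownames(expr) <- c(lnc, pcg)
    colnames(expr) <- samples
    list(expr = expr, truth = truth)
}

# Coding-gene expression from latent activity under the planted regulons.
.exprFromActivity <- function(activity, regulons, pcg, config) {
    nC <- length(pcg)
    nS <- ncol(activity)
    expr <- matrix(stats::rnorm(nC * nS), nC, nS,
                   dimnames = list(pcg, colnames(activity)))
    ti <- match(regulons$target, pcg)
    li <- match(regulons$lncrna, rownames(activity))
    eff <- regulons$sign * regulons$weight * config@signalStrength
    for (k in seq_len(nrow(regulons)))
        expr[ti[k], ] <- expr[ti[k], ] + eff[k] * activity[li[k], ]
    expr + matrix(stats::rnorm(nC * nS, sd = config@noiseSd), nC, nS)
}

#' Simulate a microarray-like compendium with survival outcomes
#'
#' Generates \code{nDatasets} cohorts over the same coding-gene universe
#' but with fresh patients: latent activities are redrawn, coding-gene
#' expression follows the planted regulons, and lncRNA rows are omitted
#' except for an optional retained subset emulating the few available
#' probes. Survival times are exponential with hazard
#' \code{baselineHazard * exp(sum(beta_l * activity_l))} and are censored by
#' an independent exponential clock (\code{censoringRate = 0} disables
#' censoring). A per-dataset affine transform (scale in U(0.8, 1.2), offset
#' in N(0, 0.5)) emulates platform differences; it is rank-preserving per
#' sample, so inferred expression is unaffected.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth the \linkS4class{GroundTruth} from
#'   \code{\link{simulateRegulatoryCohort}}.
#' @param retainLncrna character vector of lncRNA IDs to keep as measured
#'   rows (default none).
#' @return List of datasets, each a list with \code{expr},
#'   \code{survival} (sample/time/event/dataset) and \code{activity} (the
#'   latent ground truth for that dataset's patients).
#' @export
simulateMicroarrayCompendium <- function(config, truth,
                                         retainLncrna = character()) {
    stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"))
    set.seed(config@seed + 1L)
    lnc <- rownames(truth@activity)
    pcg <- .pcgIds(config@nCoding)
    stopifnot(all(truth@regulons$target %in% pcg),
              all(retainLncrna %in% lnc))
    beta <- stats::setNames(truth@prognosticLabels$beta,
                            truth@prognosticLabels$lncrna)[lnc]
    m <- config@samplesPerDataset
    lapply(seq_len(config@nDatasets), function(d) {
        ds <- sprintf("DS%02d", d)
        samples <- sprintf("%s_P%04d", ds, seq_len(m))
        activity <- matrix(stats::rnorm(length(lnc) * m), length(lnc), m,
                           dimnames = list(lnc, samples))
        expr <- .exprFromActivity(activity, truth@regulons, pcg, config)
        colnames(expr) <- samples
        if (length(retainLncrna)) {
            probe <- activity[retainLncrna, , drop = FALSE] +
                matrix(stats::rnorm(length(retainLncrna) * m,
                                    sd = config@noiseSd),
                       length(retainLncrna), m)
            expr <- rbind(probe, expr)
        }
        hazard <- config@baselineHazard *
            exp(as.vector(crossprod(activity, beta)))
        tEvent <- stats::rexp(m, rate = hazard)
        tCens <- if (config@censoringRate > 0)
            stats::rexp(m, rate = config@censoringRate) else rep(Inf, m)
        scl <- stats::runif(1, 0.8, 1.2)
        off <- stats::rnorm(1, 0, 0.5)
        list(expr = expr * scl + off,
             survival = data.frame(sample = samples,
                                   time = pmin(tEvent, tCens),
                                   event = as.integer(tEvent <= tCens),
                                   dataset = ds, stringsAsFactors = FALSE),
             activity = activity)
    })
}

#' Synthetic gene intervals on a small fixed genome
#'
#' Places genes sequentially along a small set of synthetic chromosomes
#' with a fixed gene length and inter-gene gap, round-robin across
#' chromosomes.
#'
#' @param geneIds character vector of gene IDs.
#' @param nChrom number of synthetic chromosomes (default 5).
#' @param geneLength,gap interval geometry in bases.
#' @return A \link[GenomicRanges]{GRanges} named by gene ID.
#' @export
syntheticGeneIntervals <- function(geneIds, nChrom = 5L, geneLength = 10000L,
                                   gap = 5000L) {
    n <- length(geneIds)
    chrom <- sprintf("chrS%d", ((seq_len(n) - 1L) %% nChrom) + 1L)
    slot <- (seq_len(n) - 1L) %/% nChrom
    start <- slot * (geneLength + gap) + 1L
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start, width = geneLength), strand = "*")
    names(gr) <- geneIds
    gr$gene <- geneIds
    gr
}

#' Simulate per-patient copy-number segment profiles
#'
#' Tiles each synthetic chromosome with fixed-length segments. Every
#' segment starts neutral (call 0, small Gaussian signal) and receives a
#' background alteration (+1 or -1 with equal probability) at rate
#' \code{backgroundRate}; the default of 0.25 reflects the substantial
#' fraction of a tumour genome carrying copy-number events and keeps the
#' per-patient contingency tables populated enough for the minimum-count
#' rule downstream. On top of the background, with probability
#' \code{cnaBias}, segments overlapping a hazardous locus are amplified in
#' patients whose planted activity for that lncRNA is positive, and
#' segments overlapping a protective locus are deleted in patients with
#' negative activity.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth the \linkS4class{GroundTruth}; its activity columns define
#'   the patients.
#' @param intervals \link[GenomicRanges]{GRanges} of lncRNA loci (named by
#'   gene), e.g. from \code{\link{syntheticGeneIntervals}}.
#' @param segmentLength tiling segment length in bases.
#' @param backgroundRate per-segment probability of a random alteration.
#' @return Named list (one \link[GenomicRanges]{GRanges} per patient) with
#'   metadata columns \code{signal} and \code{call}.
#' @export
simulateCnaProfiles <- function(config, truth, intervals,
                                segmentLength = 10000L,
                                backgroundRate = 0.25) {
    stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"),
              is(intervals, "GRanges"))
    lnc <- rownames(truth@activity)
    if (!all(lnc %in% names(intervals)))
        stop("every lncRNA needs an interval")
    set.seed(config@seed + 2L)
    chromLen <- vapply(
        split(GenomicRanges::end(intervals),
              as.character(GenomicRanges::seqnames(intervals))),
        max, numeric(1))
    tiles <- lapply(names(chromLen), function(ch) {
        starts <- seq(1L, chromLen[ch], by = segmentLength)
        data.frame(chrom = ch, start = starts,
                   end = pmin(starts + segmentLength - 1L, chromLen[ch]))
    })
    tiles <- do.call(rbind, tiles)
    segs <- GenomicRanges::GRanges(tiles$chrom,
                                   IRanges::IRanges(tiles$start, tiles$end))
    labels <- truth@prognosticLabels
    hazHits <- GenomicRanges::findOverlaps(
        segs, intervals[labels$lncrna[labels$label == "hazardous"]])
    proHits <- GenomicRanges::findOverlaps(
        segs, intervals[labels$lncrna[labels$label == "protective"]])
    hazLnc <- labels$lncrna[labels$label == "hazardous"]
    proLnc <- labels$lncrna[labels$label == "protective"]
    nSeg <- length(segs)
    patients <- colnames(truth@activity)
    out <- lapply(patients, function(p) {
        call <- integer(nSeg)
        signal <- stats::rnorm(nSeg, 0, 0.05)
        bg <- stats::runif(nSeg) < backgroundRate
        bgSign <- ifelse(stats::runif(nSeg) < 0.5, 1L, -1L)
        call[bg] <- bgSign[bg]
        signal[bg] <- bgSign[bg] * abs(stats::rnorm(sum(bg), 0.4, 0.1))
        if (length(hazLnc)) {
            act <- truth@activity[hazLnc, p]
            for (i in seq_along(hazLnc)) {
                if (act[i] > 0 && stats::runif(1) < config@cnaBias) {
                    si <- S4Vectors::queryHits(hazHits)[
                        S4Vectors::subjectHits(hazHits) == i]
                    call[si] <- 1L
                    signal[si] <- abs(stats::rnorm(length(si), 0.5, 0.1))
                }
            }
        }
        if (length(proLnc)) {
            act <- truth@activity[proLnc, p]
            for (i in seq_along(proLnc)) {
                if (act[i] < 0 && stats::runif(1) < config@cnaBias) {
                    si <- S4Vectors::queryHits(proHits)[
                        S4Vectors::subjectHits(proHits) == i]
                    call[si] <- -1L
                    signal[si] <- -abs(stats::rnorm(length(si), 0.5, 0.1))
                }
            }
        }
        g <- segs
        g$signal <- signal
        g$call <- call
        g
    })
    names(out) <- patients
    out
}

#' Simulate a CRISPRi-style essentiality screen
#'
#' Essential lncRNAs receive a negative mean phenotype score (growth defect
#' on knockdown), all others a mean of zero; replicate scores carry
#' Gaussian noise, and the reported p-value is a one-sample t-test across
#' replicates. With zero noise the p-value degenerates to 0 for a nonzero
#' mean and 1 otherwise.
#'
#' @param truth a \linkS4class{GroundTruth}; \code{essentialSet(truth)}
#'   defines the essential lncRNAs.
#' @param noiseSd replicate noise standard deviation.
#' @param essentialMean mean phenotype score of essential lncRNAs
#'   (negative).
#' @param nReplicates replicate screens per gene.
#' @param seed integer RNG seed.
#' @return data.frame: \code{gene}, \code{avg_phenotype_score}, \code{p}.
#' @export
simulateEssentialityScreen <- function(truth, noiseSd = 0.2,
                                       essentialMean = -0.5,
                                       nReplicates = 8L, seed = 1L) {
    stopifnot(is(truth, "GroundTruth"))
    lnc <- rownames(truth@activity)
    stopifnot(all(truth@essentialSet %in% lnc))
    set.seed(seed)
    mu <- ifelse(lnc %in% truth@essentialSet, essentialMean, 0)
    scores <- vapply(mu, function(m) {
        reps <- m + stats::rnorm(nReplicates, sd = noiseSd)
        s <- stats::sd(reps)
        p <- if (s == 0) {
            if (mean(reps) != 0) 0 else 1
        } else stats::t.test(reps)$p.value
        c(mean(reps), p)
    }, numeric(2))
    data.frame(gene = lnc, avg_phenotype_score = scores[1L, ],
               p = scores[2L, ], stringsAsFactors = FALSE)
}

#' Weight profiles from the planted ground truth
#'
#' Builds the up/down weight profiles a perfect regulon-inference run would
#' produce: planted weights normalised by the regulon maximum and split by
#' planted sign. Useful for testing the inference and screening stages in
#' isolation from network learning.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param geneUniverse gene universe for the profiles (defaults to the
#'   planted coding genes).
#' @param minGenes minimum profile size, as in
#'   \code{\link{makeWeightProfiles}}.
#' @return Named list of \linkS4class{WeightProfiles}.
#' @export
trueWeightProfiles <- function(truth, geneUniverse = NULL, minGenes = 20L) {
    stopifnot(is(truth, "GroundTruth"))
    if (is.null(geneUniverse))
        geneUniverse <- sort(unique(truth@regulons$target))
    out <- lapply(split(truth@regulons, truth@regulons$lncrna), function(d) {
        w <- d$weight / max(d$weight)
        r <- new("Regulon", lncrna = d$lncrna[1L],
                 targets = data.frame(target = d$target, mi = d$weight,
                                      weight = w, sign = d$sign,
                                      stringsAsFactors = FALSE))
        makeWeightProfiles(r, geneUniverse, minGenes)
    })
    out[rownames(truth@activity)[rownames(truth@activity) %in% names(out)]]
}
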