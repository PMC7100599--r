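#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors DataFrame metadata
#' @import data.table
#' @importFrom stats setNames
#' @useDynLib lncProg, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic cohort generator
#'
#' Holds every tunable of the synthetic-data module: cohort dimensions,
#' regulon geometry, signal and noise scales, planted survival effects,
#' copy-number bias and the RNG seed. The defaults define the standard
#' synthetic cohort used throughout the package's recovery tests.
#'
#' @slot nLncrna,nCoding number of lncRNA regulators and coding genes.
#' @slot nSamplesRnaseq samples in the RNA-seq-like training cohort.
#' @slot nDatasets,samplesPerDataset microarray-like compendium geometry.
#' @slot regulonSizeMean mean planted regulon size (Poisson).
#' @slot fracNegativeEdges fraction of negatively-signed regulon edges.
#' @slot signalStrength multiplier on the regulator activity in targets.
#' @slot noiseSd standard deviation of the measurement noise.
#' @slot nHazardous,nProtective numbers of planted prognostic lncRNAs.
#' @slot betaMagnitude absolute Cox log hazard ratio of planted effects.
#' @slot baselineHazard baseline exponential event rate.
#' @slot censoringRate exponential censoring rate (0 disables censoring).
#' @slot cnaBias probability that a prognostic locus receives the
#'   concordant copy-number event in a concordant patient.
#' @slot seed integer RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nLncrna = "integer", nCoding = "integer",
        nSamplesRnaseq = "integer", nDatasets = "integer",
        samplesPerDataset = "integer", regulonSizeMean = "numeric",
        fracNegativeEdges = "numeric", signalStrength = "numeric",
        noiseSd = "numeric", nHazardous = "integer", nProtective = "integer",
        betaMagnitude = "numeric", baselineHazard = "numeric",
        censoringRate = "numeric", cnaBias = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    pos <- c(nLncrna = object@nLncrna, nCoding = object@nCoding,
             nSamplesRnaseq = object@nSamplesRnaseq,
             nDatasets = object@nDatasets,
             samplesPerDataset = object@samplesPerDataset)
    if (any(pos < 1))
        msg <- c(msg, "cohort dimensions must be positive integers")
    if (object@regulonSizeMean <= 0)
        msg <- c(msg, "regulonSizeMean must be > 0")
    if (object@fracNegativeEdges < 0 || object@fracNegativeEdges > 1)
        msg <- c(msg, "fracNegativeEdges must lie in [0, 1]")
    if (object@signalStrength < 0) msg <- c(msg, "signalStrength must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@nHazardous < 0 || object@nProtective < 0)
        msg <- c(msg, "planted effect counts must be >= 0")
    if (object@nHazardous + object@nProtective > object@nLncrna)
        msg <- c(msg, "nHazardous + nProtective must not exceed nLncrna")
    if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
    if (object@censoringRate < 0) msg <- c(msg, "censoringRate must be >= 0")
    if (object@cnaBias < 0 || object@cnaBias > 1)
        msg <- c(msg, "cnaBias must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nLncrna,nCoding,nSamplesRnaseq,nDatasets,samplesPerDataset cohort
#'   dimensions.
#' @param regulonSizeMean,fracNegativeEdges,signalStrength,noiseSd regulon
#'   geometry and noise.
#' @param nHazardous,nProtective,betaMagnitude,baselineHazard,censoringRate
#'   survival generator settings.
#' @param cnaBias copy-number concordance probability.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(nLncrna = 5, nCoding = 100, seed = 1)
#' @export
simConfig <- function(nLncrna = 50L, nCoding = 5000L,
                      nSamplesRnaseq = 200L, nDatasets = 3L,
                      samplesPerDataset = 150L, regulonSizeMean = 30,
                      fracNegativeEdges = 0.3, signalStrength = 1,
                      noiseSd = 0.5, nHazardous = 5L, nProtective = 5L,
                      betaMagnitude = 0.8, baselineHazard = 0.1,
                      censoringRate = 0.05, cnaBias = 0.9, seed = 1L) {
    new("SimulationConfig",
        nLncrna = as.integer(nLncrna), nCoding = as.integer(nCoding),
        nSamplesRnaseq = as.integer(nSamplesRnaseq),
        nDatasets = as.integer(nDatasets),
        samplesPerDataset = as.integer(samplesPerDataset),
        regulonSizeMean = as.numeric(regulonSizeMean),
        fracNegativeEdges = as.numeric(fracNegativeEdges),
        signalStrength = as.numeric(signalStrength),
        noiseSd = as.numeric(noiseSd),
        nHazardous = as.integer(nHazardous),
        nProtective = as.integer(nProtective),
        betaMagnitude = as.numeric(betaMagnitude),
        baselineHazard = as.numeric(baselineHazard),
        censoringRate = as.numeric(censoringRate),
        cnaBias = as.numeric(cnaBias), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nLncrna, "lncRNAs,",
        object@nCoding, "coding genes,", object@nSamplesRnaseq,
        "RNA-seq samples\n  compendium:", object@nDatasets, "datasets x",
        object@samplesPerDataset, "samples; seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' Planted structure of a synthetic cohort
#'
#' Records everything the generator planted: the latent regulator activity,
#' the regulon edge table with true signs and weights, the prognostic label
#' and true log hazard ratio of every lncRNA, and the essential set.
#'
#' @slot activity lncRNA-by-sample latent activity matrix.
#' @slot regulons data.frame with columns \code{lncrna}, \code{target},
#'   \code{sign}, \code{weight}.
#' @slot prognosticLabels data.frame with columns \code{lncrna},
#'   \code{label} (hazardous/protective/null) and \code{beta}.
#' @slot essentialSet character vector of essential lncRNA IDs.
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(activity = "matrix", regulons = "data.frame",
                   prognosticLabels = "data.frame",
                   essentialSet = "character"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (!all(c("lncrna", "target", "sign", "weight") %in%
             colnames(object@regulons)))
        msg <- c(msg, "regulons must have lncrna/target/sign/weight columns")
    else if (nrow(object@regulons) &&
             !all(object@regulons$sign %in% c(-1, 1)))
        msg <- c(msg, "regulon signs must be +1 or -1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@activity), "lncRNAs,",
        nrow(object@regulons), "planted edges,",
        sum(object@prognosticLabels$label == "hazardous"), "hazardous /",
        sum(object@prognosticLabels$label == "protective"),
        "protective planted effects\n")
})

#' @describeIn GroundTruth latent activity matrix accessor
#' @param x a \code{GroundTruth}
#' @export
trueActivity <- function(x) x@activity

#' @describeIn GroundTruth planted regulon edge table accessor
#' @export
trueRegulons <- function(x) x@regulons

#' @describeIn GroundTruth planted prognostic label accessor
#' @export
prognosticLabels <- function(x) x@prognosticLabels

#' @describeIn GroundTruth planted essential lncRNA set accessor
#' @export
essentialSet <- function(x) x@essentialSet

# ---------------------------------------------------------------------------
# MINetwork
# ---------------------------------------------------------------------------

#' Mutual information network
#'
#' An edge list of regulator-gene dependencies with mutual information in
#' nats and, after bootstrap consensus, the number of supporting bootstraps.
#'
#' @slot edges data.frame with columns \code{regulator}, \code{target},
#'   \code{mi}, \code{support}.
#' @slot nBootstrap number of bootstrap iterations that produced the network.
#' @exportClass MINetwork
setClass("MINetwork",
    representation(edges = "data.frame", nBootstrap = "integer"))

setValidity("MINetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("regulator", "target", "mi", "support") %in% colnames(e)))
        msg <- c(msg, "edges must have regulator/target/mi/support columns")
    else {
        if (nrow(e) && any(e$regulator == e$target))
            msg <- c(msg, "self-edges are not allowed")
        if (nrow(e) && any(e$mi < 0)) msg <- c(msg, "mi must be >= 0")
        if (nrow(e) && any(e$support > object@nBootstrap))
            msg <- c(msg, "support cannot exceed nBootstrap")
    }
    if (length(msg)) msg else TRUE
})

MINetwork <- function(edges, nBootstrap = 1L) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!"support" %in% colnames(edges)) edges$support <- 1L
    rownames(edges) <- NULL
    new("MINetwork", edges = edges, nBootstrap = as.integer(nBootstrap))
}

#' @describeIn MINetwork edge table accessor
#' @param x an \code{MINetwork}
#' @export
networkEdges <- function(x) x@edges

setMethod("show", "MINetwork", function(object) {
    cat("MINetwork:", nrow(object@edges), "edges over",
        length(unique(object@edges$regulator)), "regulators (",
        object@nBootstrap, "bootstraps )\n")
})

# ---------------------------------------------------------------------------
# Regulon and weight profiles
# ---------------------------------------------------------------------------

#' A lncRNA regulon
#'
#' A regulator with its associated genes; weights are mutual information
#' scores divided by the regulon maximum (so the largest is exactly 1) and
#' signs come from the Pearson correlation between regulator and target.
#'
#' @slot lncrna regulator gene ID.
#' @slot targets data.frame with columns \code{target}, \code{mi},
#'   \code{weight}, \code{sign}.
#' @exportClass Regulon
setClass("Regulon",
    representation(lncrna = "character", targets = "data.frame"))

setValidity("Regulon", function(object) {
    t <- object@targets
    msg <- character()
    if (!all(c("target", "mi", "weight", "sign") %in% colnames(t)))
        msg <- c(msg, "targets must have target/mi/weight/sign columns")
    else if (nrow(t)) {
        if (abs(max(t$weight) - 1) > 1e-12)
            msg <- c(msg, "maximum weight must equal 1")
        if (any(t$weight <= 0) || any(t$weight > 1 + 1e-12))
            msg <- c(msg, "weights must lie in (0, 1]")
        if (!all(t$sign %in% c(-1, 1)))
            msg <- c(msg, "signs must be +1 or -1")
        if (object@lncrna %in% t$target)
            msg <- c(msg, "a regulon cannot contain its own regulator")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn Regulon signed weighted target table accessor
#' @param x a \code{Regulon}
#' @export
regulonTargets <- function(x) x@targets

setMethod("show", "Regulon", function(object) {
    cat("Regulon", object@lncrna, ":", nrow(object@targets), "targets (",
        sum(object@targets$sign > 0), "positive /",
        sum(object@targets$sign < 0), "negative )\n")
})

#' Up/down weight profiles of a regulon
#'
#' The non-negative split of a signed regulon over the gene universe:
#' positively-signed weights form the up profile and the magnitudes of
#' negatively-signed weights the down profile. A profile with fewer than
#' \code{minGenes} members is flagged invalid and contributes nothing
#' downstream.
#'
#' @slot lncrna regulator gene ID.
#' @slot up,down named non-negative weight vectors (nonzero entries only).
#' @slot upValid,downValid validity flags.
#' @slot universe the gene universe the profiles are defined over.
#' @exportClass WeightProfiles
setClass("WeightProfiles",
    representation(lncrna = "character", up = "numeric", down = "numeric",
                   upValid = "logical", downValid = "logical",
                   universe = "character"))

setValidity("WeightProfiles", function(object) {
    msg <- character()
    if (length(intersect(names(object@up), names(object@down))))
        msg <- c(msg, "up and down supports must be disjoint")
    w <- c(object@up, object@down)
    if (length(w) && (any(w <= 0) || any(w > 1 + 1e-12)))
        msg <- c(msg, "nonzero weights must lie in (0, 1]")
    if (!all(c(names(object@up), names(object@down)) %in% object@universe))
        msg <- c(msg, "profile genes must belong to the universe")
    if (length(msg)) msg else TRUE
})

#' @describeIn WeightProfiles up-profile weights (named, nonzero entries)
#' @param x a \code{WeightProfiles}
#' @export
upProfile <- function(x) x@up

#' @describeIn WeightProfiles down-profile weights (named, nonzero entries)
#' @export
downProfile <- function(x) x@down

#' @describeIn WeightProfiles TRUE unless both profiles are invalid
#' @export
isInferable <- function(x) x@upValid || x@downValid

setMethod("show", "WeightProfiles", function(object) {
    cat("WeightProfiles", object@lncrna, ": up", length(object@up),
        if (object@upValid) "(valid)" else "(invalid)",
        "/ down", length(object@down),
        if (object@downValid) "(valid)" else "(invalid)", "\n")
})

# ---------------------------------------------------------------------------
# IExprMatrix
# ---------------------------------------------------------------------------

#' Inferred lncRNA expression matrix
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with assays
#' \code{iexpr} (null-normalised inferred expression) and \code{preIexpr}
#' (raw signed deviation). Row metadata records the profile sizes, the
#' low-coverage flag and the number of genes dropped because they were
#' absent from the target array.
#'
#' @exportClass IExprMatrix
setClass("IExprMatrix", contains = "SummarizedExperiment")

#' @describeIn IExprMatrix inferred-expression assay accessor
#' @param x an \code{IExprMatrix}
#' @export
iexpr <- function(x) SummarizedExperiment::assay(x, "iexpr")

#' @describeIn IExprMatrix raw pre-iExpr assay accessor
#' @export
preIexpr <- function(x) SummarizedExperiment::assay(x, "preIexpr")
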