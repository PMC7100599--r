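# Readers and writers for the pipeline's tab-separated formats.
#
# Floats are serialised with 17 significant digits so that every written
# value survives a read round-trip exactly. BED files are 0-based
# half-open on disk (rtracklayer handles the conversion to the 1-based
# in-memory ranges); SEG files default to the same convention with an
# explicit dialect flag for 1-based-inclusive inputs.

.fmt <- function(x) {
    if (is.double(x)) sprintf("%.17g", x) else x
}

.writeTsv <- function(df, path) {
    out <- data.table::as.data.table(lapply(df, .fmt))
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    invisible(path)
}

.readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0) stop("empty or malformed file: ", path)
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    if (nrow(df) == 0L && ncol(df) == 0L)
        stop("empty or malformed file: ", path)
    df
}

#' Read / write a gene-by-sample expression matrix TSV
#'
#' The on-disk format has genes in rows, a header of sample IDs, and the
#' gene ID in the first column (\code{gene}). Values round-trip exactly.
#'
#' @param path file path.
#' @return \code{readExpressionTsv}: numeric matrix with gene rownames and
#'   sample colnames.
#' @export
readExpressionTsv <- function(path) {
    df <- .readTsv(path)
    if (colnames(df)[1L] != "gene")
        stop("malformed header: first column must be 'gene'")
    if (ncol(df) < 2L) stop("expression file has no sample columns")
    genes <- as.character(df[[1L]])
    if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
        bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
        stop("non-numeric expression values in column '",
             colnames(df)[bad + 1L], "'")
    }
    rownames(m) <- genes
    m
}

#' @rdname readExpressionTsv
#' @param expr gene-by-sample numeric matrix with dimnames.
#' @export
writeExpressionTsv <- function(expr, path) {
    expr <- .checkExprMatrix(expr)
    df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTsv(df, path)
}

#' Read / write a survival table TSV
#'
#' Columns \code{sample}, \code{time}, \code{event}, \code{dataset} plus
#' any covariate columns. Validation rejects non-positive times and event
#' codes outside {0, 1}, naming the offending row.
#'
#' @param path file path.
#' @return \code{readSurvivalTsv}: validated data.frame.
#' @export
readSurvivalTsv <- function(path) {
    df <- .readTsv(path)
    need <- c("sample", "time", "event")
    if (!all(need %in% colnames(df)))
        stop("survival file must have columns: ",
             paste(need, collapse = ", "))
    bad <- which(df$time <= 0)
    if (length(bad))
        stop("non-positive follow-up time at row ", bad[1L])
    bad <- which(!df$event %in% c(0, 1))
    if (length(bad))
        stop("invalid event code at row ", bad[1L])
    df
}

#' @rdname readSurvivalTsv
#' @param surv survival data.frame.
#' @export
writeSurvivalTsv <- function(surv, path) {
    .checkSurvivalTable(surv)
    .writeTsv(surv, path)
}

#' Read / write a regulon network TSV
#'
#' Columns: \code{regulator}, \code{target}, \code{mi}, \code{weight},
#' \code{sign}, \code{bootstrap_support}. One row per signed weighted edge,
#' from one or several \linkS4class{Regulon} objects.
#'
#' @param path file path.
#' @return \code{readRegulonTsv}: named list of \linkS4class{Regulon}.
#' @export
readRegulonTsv <- function(path) {
    df <- .readTsv(path)
    need <- c("regulator", "target", "mi", "weight", "sign",
              "bootstrap_support")
    if (!all(need %in% colnames(df)))
        stop("regulon file must have columns: ",
             paste(need, collapse = ", "))
    lapply(split(df, df$regulator), function(d) {
        new("Regulon", lncrna = d$regulator[1L],
            targets = data.frame(target = d$target, mi = d$mi,
                                 weight = d$weight, sign = d$sign,
                                 support = d$bootstrap_support,
                                 stringsAsFactors = FALSE))
    })
}

#' @rdname readRegulonTsv
#' @param regulons a \linkS4class{Regulon} or list of them.
#' @export
writeRegulonTsv <- function(regulons, path) {
    if (is(regulons, "Regulon")) regulons <- list(regulons)
    df <- do.call(rbind, lapply(regulons, function(r) {
        t <- r@targets
        data.frame(regulator = r@lncrna, target = t$target, mi = t$mi,
                   weight = t$weight, sign = t$sign,
                   bootstrap_support = if ("support" %in% colnames(t))
                       t$support else NA_integer_,
                   stringsAsFactors = FALSE)
    }))
    .writeTsv(df, path)
}

#' Read / write weight profiles TSV
#'
#' Long format with columns \code{lncrna}, \code{gene}, \code{up_weight},
#' \code{down_weight} (nonzero entries only) plus per-lncRNA validity
#' columns \code{up_valid}, \code{down_valid}.
#'
#' @param path file path.
#' @param universe gene universe to attach on read.
#' @return \code{readProfilesTsv}: named list of
#'   \linkS4class{WeightProfiles}.
#' @export
readProfilesTsv <- function(path, universe) {
    df <- .readTsv(path)
    need <- c("lncrna", "gene", "up_weight", "down_weight", "up_valid",
              "down_valid")
    if (!all(need %in% colnames(df)))
        stop("profiles file must have columns: ",
             paste(need, collapse = ", "))
    lapply(split(df, df$lncrna), function(d) {
        up <- d$up_weight > 0
        new("WeightProfiles", lncrna = d$lncrna[1L],
            up = stats::setNames(d$up_weight[up], d$gene[up]),
            down = stats::setNames(d$down_weight[!up], d$gene[!up]),
            upValid = as.logical(d$up_valid[1L]),
            downValid = as.logical(d$down_valid[1L]),
            universe = as.character(universe))
    })
}

#' @rdname readProfilesTsv
#' @param profiles a list of \linkS4class{WeightProfiles}.
#' @export
writeProfilesTsv <- function(profiles, path) {
    if (is(profiles, "WeightProfiles")) profiles <- list(profiles)
    df <- do.call(rbind, lapply(profiles, function(p) {
        data.frame(lncrna = p@lncrna,
                   gene = c(names(p@up), names(p@down)),
                   up_weight = c(unname(p@up), rep(0, length(p@down))),
                   down_weight = c(rep(0, length(p@up)), unname(p@down)),
                   up_valid = p@upValid, down_valid = p@downValid,
                   stringsAsFactors = FALSE)
    }))
    .writeTsv(df, path)
}

#' Read / write gene intervals as BED
#'
#' BED is 0-based half-open on disk; in memory the intervals are 1-based
#' \link[GenomicRanges]{GRanges} (a record \code{chr1 100 200} becomes
#' start 101, end 200, width 100).
#'
#' @param path file path.
#' @return \code{readBed}: \link[GenomicRanges]{GRanges} named by the BED
#'   name column.
#' @export
readBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(gr$name)) {
        names(gr) <- gr$name
        gr$gene <- gr$name
    }
    gr
}

#' @rdname readBed
#' @param gr \link[GenomicRanges]{GRanges} named by gene.
#' @export
writeBed <- function(gr, path) {
    stopifnot(is(gr, "GRanges"))
    out <- gr
    out$name <- if (!is.null(names(gr))) names(gr) else gr$gene
    out$gene <- NULL
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read / write per-patient CNA segments (SEG-style TSV)
#'
#' Columns: \code{patient}, \code{chrom}, \code{start}, \code{end},
#' \code{signal}, \code{call}. The default on-disk dialect is 0-based
#' half-open; \code{dialect = "one_based"} imports 1-based-inclusive
#' coordinates. Calls must be -1, 0 or +1.
#'
#' @param path file path.
#' @param dialect \code{"zero_half_open"} (default) or \code{"one_based"}.
#' @return \code{readSegTsv}: named list of per-patient
#'   \link[GenomicRanges]{GRanges} with \code{signal} and \code{call}.
#' @export
readSegTsv <- function(path, dialect = c("zero_half_open", "one_based")) {
    dialect <- match.arg(dialect)
    df <- .readTsv(path)
    need <- c("patient", "chrom", "start", "end", "signal", "call")
    if (!all(need %in% colnames(df)))
        stop("SEG file must have columns: ", paste(need, collapse = ", "))
    bad <- which(!df$call %in% c(-1, 0, 1))
    if (length(bad)) stop("unknown CNA call at row ", bad[1L])
    start1 <- if (dialect == "zero_half_open") df$start + 1L else df$start
    bad <- which(start1 > df$end)
    if (length(bad)) stop("invalid segment coordinates at row ", bad[1L])
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(start1, df$end))
    gr$signal <- df$signal
    gr$call <- as.integer(df$call)
    out <- split(gr, df$patient)
    lapply(out, identity)
}

#' @rdname readSegTsv
#' @param profiles named list of per-patient segment
#'   \link[GenomicRanges]{GRanges}.
#' @export
writeSegTsv <- function(profiles, path,
                        dialect = c("zero_half_open", "one_based")) {
    dialect <- match.arg(dialect)
    df <- do.call(rbind, lapply(names(profiles), function(p) {
        g <- profiles[[p]]
        start <- GenomicRanges::start(g)
        data.frame(patient = p,
                   chrom = as.character(GenomicRanges::seqnames(g)),
                   start = if (dialect == "zero_half_open") start - 1L
                           else start,
                   end = GenomicRanges::end(g), signal = g$signal,
                   call = g$call, stringsAsFactors = FALSE)
    }))
    .writeTsv(df, path)
}

#' Read / write a phenotype-score table TSV
#'
#' Columns: \code{gene}, \code{avg_phenotype_score}, \code{p}.
#'
#' @param path file path.
#' @return \code{readPhenotypeTsv}: data.frame.
#' @export
readPhenotypeTsv <- function(path) {
    df <- .readTsv(path)
    need <- c("gene", "avg_phenotype_score", "p")
    if (!all(need %in% colnames(df)))
        stop("phenotype file must have columns: ",
             paste(need, collapse = ", "))
    df
}

#' @rdname readPhenotypeTsv
#' @param screen phenotype-score data.frame.
#' @export
writePhenotypeTsv <- function(screen, path) .writeTsv(screen, path)

#' Read / write an inferred-expression (iExpr) table TSV
#'
#' Long format: \code{lncrna}, \code{sample}, \code{pre_iexpr},
#' \code{iexpr}, \code{n_perm}.
#'
#' @param path file path.
#' @return \code{readIExprTsv}: data.frame.
#' @export
readIExprTsv <- function(path) {
    df <- .readTsv(path)
    need <- c("lncrna", "sample", "pre_iexpr", "iexpr", "n_perm")
    if (!all(need %in% colnames(df)))
        stop("iExpr file must have columns: ", paste(need, collapse = ", "))
    df
}

#' @rdname readIExprTsv
#' @param ie an \linkS4class{IExprMatrix}.
#' @export
writeIExprTsv <- function(ie, path) {
    stopifnot(is(ie, "IExprMatrix"))
    m <- iexpr(ie)
    p <- preIexpr(ie)
    df <- data.frame(lncrna = rep(rownames(m), times = ncol(m)),
                     sample = rep(colnames(m), each = nrow(m)),
                     pre_iexpr = as.vector(p), iexpr = as.vector(m),
                     n_perm = S4Vectors::metadata(ie)$nPerm,
                     stringsAsFactors = FALSE)
    .writeTsv(df, path)
}
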