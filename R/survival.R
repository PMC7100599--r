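# Cox screening, Stouffer meta-analysis, multiple-testing adjustment,
# Kaplan-Meier / log-rank utilities.

.checkSurvivalTable <- function(surv) {
    need <- c("sample", "time", "event")
    if (!all(need %in% colnames(surv)))
        stop("survival table must have columns: ",
             paste(need, collapse = ", "))
    if (any(surv$time <= 0)) stop("follow-up times must be > 0")
    if (!all(surv$event %in% c(0, 1)))
        stop("event indicator must be 0 (censored) or 1 (death)")
    if (anyDuplicated(surv$sample))
        stop("duplicate sample identifiers in survival table")
    surv
}

.coxFitRecord <- function(beta, se, n, converged) {
    z <- beta / se
    data.frame(beta = beta, se = se, z = z, hr = exp(beta),
               p = 2 * stats::pnorm(-abs(z)), n = n, converged = converged)
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits \code{Surv(time, event) ~ x} by partial-likelihood maximisation with
#' Efron tie handling and returns the coefficient, its standard error and
#' the Wald z-score \code{beta/se}. Positive z marks a hazardous covariate
#' (higher values, higher mortality), negative z a protective one.
#'
#' @param x numeric expression vector aligned with \code{surv$sample}.
#' @param surv data.frame with columns \code{sample}, \code{time},
#'   \code{event}.
#' @return One-row data.frame: \code{beta}, \code{se}, \code{z}, \code{hr},
#'   \code{p}, \code{n}, \code{converged}.
#' @export
fitUnivariateCox <- function(x, surv) {
    surv <- .checkSurvivalTable(surv)
    if (length(x) != nrow(surv))
        stop("x must align with the survival table")
    ok <- is.finite(x)
    x <- x[ok]
    surv <- surv[ok, , drop = FALSE]
    if (sum(surv$event) < 2L)
        stop("degenerate fit: fewer than 2 events")
    if (stats::sd(x) == 0)
        stop("degenerate fit: constant covariate")
    ctrl <- survival::coxph.control(iter.max = 50L, eps = 1e-9)
    fit <- survival::coxph.fit(
        x = matrix(x, ncol = 1L), y = survival::Surv(surv$time, surv$event),
        strata = NULL, offset = NULL, init = 0, control = ctrl,
        weights = NULL, method = "efron", rownames = NULL)
    beta <- unname(fit$coefficients)
    se <- sqrt(unname(fit$var[1L, 1L]))
    conv <- is.finite(beta) && is.finite(se) && abs(beta) < 20 &&
        fit$iter < ctrl$iter.max
    .coxFitRecord(beta, se, length(x), conv)
}

#' Covariate-adjusted Cox fit for one expression vector
#'
#' Fits a multiple Cox regression of survival on the expression vector plus
#' clinical covariates (complete-case) and returns the record for the
#' expression coefficient.
#'
#' @param x numeric expression vector aligned with \code{surv$sample}.
#' @param covariates data.frame of numeric covariate columns aligned with
#'   \code{surv$sample}; all-zero or all-constant columns are dropped.
#' @param surv survival table as in \code{\link{fitUnivariateCox}}.
#' @return One-row data.frame as in \code{\link{fitUnivariateCox}}.
#' @export
fitMultivariateCox <- function(x, covariates, surv) {
    surv <- .checkSurvivalTable(surv)
    covariates <- as.data.frame(covariates)
    if (length(x) != nrow(surv) ||
        (ncol(covariates) && nrow(covariates) != nrow(surv)))
        stop("x and covariates must align with the survival table")
    keepCol <- vapply(covariates, function(v)
        stats::sd(v, na.rm = TRUE) > 0, logical(1))
    covariates <- covariates[, keepCol, drop = FALSE]
    cc <- stats::complete.cases(cbind(x, covariates))
    x <- x[cc]
    covariates <- covariates[cc, , drop = FALSE]
    surv <- surv[cc, , drop = FALSE]
    if (sum(surv$event) < 2L)
        stop("degenerate fit: fewer than 2 events")
    X <- cbind(x = x, as.matrix(covariates))
    qrX <- qr(scale(X, scale = FALSE))
    if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
        stop("collinear design: ", paste(bad, collapse = ", "))
    }
    ctrl <- survival::coxph.control(iter.max = 50L, eps = 1e-9)
    fit <- survival::coxph.fit(
        x = X, y = survival::Surv(surv$time, surv$event), strata = NULL,
        offset = NULL, init = rep(0, ncol(X)), control = ctrl,
        weights = NULL, method = "efron", rownames = NULL)
    beta <- unname(fit$coefficients[1L])
    se <- sqrt(fit$var[1L, 1L])
    conv <- is.finite(beta) && is.finite(se) && abs(beta) < 20 &&
        fit$iter < ctrl$iter.max
    .coxFitRecord(beta, se, nrow(surv), conv)
}

#' Weighted Stouffer combination of z-scores
#'
#' \code{metaZ = sum(w * z) / sqrt(sum(w^2))} with weights equal to the
#' dataset sample sizes (default) or their square roots. Scale-free in the
#' weights: multiplying all weights by a constant leaves the result
#' unchanged.
#'
#' @param zs numeric vector of per-dataset z-scores.
#' @param ns positive dataset sample sizes, same length as \code{zs}.
#' @param weightMode \code{"n"} (default) or \code{"sqrt_n"}.
#' @return The combined meta z-score.
#' @export
stoufferMeta <- function(zs, ns, weightMode = c("n", "sqrt_n")) {
    weightMode <- match.arg(weightMode)
    if (length(zs) == 0L) stop("empty z-score vector")
    if (length(zs) != length(ns)) stop("zs and ns must align")
    if (any(ns <= 0)) stop("sample sizes must be positive")
    w <- if (weightMode == "n") as.numeric(ns) else sqrt(as.numeric(ns))
    sum(w * zs) / sqrt(sum(w^2))
}

#' Robust leave-one-out Stouffer meta z-score
#'
#' Drops the dataset with the most significant association (largest |z|;
#' ties broken by the first dataset in lexicographic ID order) and
#' recombines the remainder.
#'
#' @param zs named numeric vector of per-dataset z-scores (names are
#'   dataset IDs).
#' @param ns dataset sample sizes aligned with \code{zs}.
#' @param weightMode as in \code{\link{stoufferMeta}}.
#' @return List with \code{robustMetaZ} and \code{leftOutDataset}; with
#'   fewer than 2 datasets the robust score is \code{NA} with an empty
#'   left-out ID.
#' @export
robustMeta <- function(zs, ns, weightMode = c("n", "sqrt_n")) {
    weightMode <- match.arg(weightMode)
    if (length(zs) < 2L)
        return(list(robustMetaZ = NA_real_, leftOutDataset = NA_character_))
    ids <- if (is.null(names(zs))) as.character(seq_along(zs)) else names(zs)
    ord <- order(ids)
    zs <- zs[ord]; ns <- ns[ord]; ids <- ids[ord]
    out <- which.max(abs(zs))  # first in ID order on ties
    list(robustMetaZ = stoufferMeta(zs[-out], ns[-out], weightMode),
         leftOutDataset = ids[out])
}

#' Adjust p-values for multiple testing
#'
#' Standard step-up Benjamini-Hochberg with monotonicity enforcement, or
#' Bonferroni \code{min(1, m * p)}. Adjustment is intended to be applied
#' within one cancer-type family at a time.
#'
#' @param ps numeric vector of p-values in (0, 1].
#' @param method \code{"BH"} or \code{"bonferroni"}.
#' @return Adjusted p-values.
#' @export
adjustPvalues <- function(ps, method = c("BH", "bonferroni")) {
    method <- match.arg(method)
    if (any(!is.finite(ps)) || any(ps <= 0) || any(ps > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(ps, method = method)
}

#' Per-dataset Cox screen of an inferred-expression matrix
#'
#' Fits a univariate Cox model to every lncRNA row against the dataset's
#' survival table. Rows that cannot be fit (constant values, too few
#' events) are returned with NA statistics.
#'
#' @param iexprMat lncRNA-by-sample numeric matrix (e.g.
#'   \code{iexpr(inferExpression(...))}).
#' @param surv survival table whose \code{sample} column matches the matrix
#'   columns; a \code{dataset} column labels the dataset.
#' @return data.frame: \code{lncrna}, \code{dataset}, \code{n},
#'   \code{beta}, \code{se}, \code{z}, \code{hr}, \code{p}.
#' @export
screenSurvival <- function(iexprMat, surv) {
    if (is(iexprMat, "IExprMatrix")) iexprMat <- iexpr(iexprMat)
    surv <- .checkSurvivalTable(surv)
    m <- match(surv$sample, colnames(iexprMat))
    if (anyNA(m))
        stop("survival samples missing from the expression matrix")
    iexprMat <- iexprMat[, m, drop = FALSE]
    ds <- if ("dataset" %in% colnames(surv)) surv$dataset[1L] else "dataset1"
    rows <- lapply(rownames(iexprMat), function(l) {
        fit <- tryCatch(fitUnivariateCox(iexprMat[l, ], surv),
                        error = function(e) NULL)
        if (is.null(fit))
            fit <- data.frame(beta = NA_real_, se = NA_real_, z = NA_real_,
                              hr = NA_real_, p = NA_real_,
                              n = nrow(surv), converged = FALSE)
        cbind(data.frame(lncrna = l, dataset = ds,
                         stringsAsFactors = FALSE), fit)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("lncrna", "dataset", "n", "beta", "se", "z", "hr", "p")]
}

#' Combine per-dataset Cox screens into meta z-scores
#'
#' For every lncRNA the per-dataset z-scores are combined by weighted
#' Stouffer meta-analysis (dataset sample sizes as weights), a robust
#' leave-one-out meta z is computed, the meta p-value is taken from the
#' standard normal, and BH and Bonferroni adjustments are applied across
#' the lncRNAs of this family (one cancer type).
#'
#' @param screens data.frame as returned by \code{\link{screenSurvival}},
#'   rows from all datasets of one family.
#' @param weightMode as in \code{\link{stoufferMeta}}.
#' @return data.frame: \code{lncrna}, \code{nDatasets}, \code{metaZ},
#'   \code{robustMetaZ}, \code{leftOutDataset}, \code{metaP}, \code{fdrBH},
#'   \code{bonferroni}.
#' @export
metaAnalyze <- function(screens, weightMode = c("n", "sqrt_n")) {
    weightMode <- match.arg(weightMode)
    screens <- screens[is.finite(screens$z), , drop = FALSE]
    if (nrow(screens) == 0L) stop("no usable per-dataset fits")
    rows <- lapply(split(screens, screens$lncrna), function(d) {
        zs <- stats::setNames(d$z, d$dataset)
        mz <- stoufferMeta(zs, d$n, weightMode)
        rb <- robustMeta(zs, d$n, weightMode)
        data.frame(lncrna = d$lncrna[1L], nDatasets = nrow(d), metaZ = mz,
                   robustMetaZ = rb$robustMetaZ,
                   leftOutDataset = rb$leftOutDataset,
                   metaP = 2 * stats::pnorm(-abs(mz)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$fdrBH <- adjustPvalues(out$metaP, "BH")
    out$bonferroni <- adjustPvalues(out$metaP, "bonferroni")
    out
}

#' Kaplan-Meier comparison of high vs low inferred expression
#'
#' Dichotomises patients into high (iExpr > threshold) and low (iExpr <=
#' threshold; exact zeros fall in the low group) and performs a two-group
#' log-rank test. Also emits the Kaplan-Meier step-function table of each
#' group for plotting.
#'
#' @param iexprVec numeric inferred-expression vector aligned with
#'   \code{surv$sample}.
#' @param surv survival table.
#' @param threshold dichotomisation threshold (default 0).
#' @return List: \code{chiSquare}, \code{p}, \code{groupSizes},
#'   \code{curves} (data.frame with group, time, nRisk, nEvent, surv).
#' @export
kmLogrank <- function(iexprVec, surv, threshold = 0) {
    surv <- .checkSurvivalTable(surv)
    if (length(iexprVec) != nrow(surv))
        stop("expression vector must align with the survival table")
    group <- factor(ifelse(iexprVec > threshold, "high", "low"),
                    levels = c("low", "high"))
    if (any(table(group) == 0L))
        stop("degenerate test: one expression group is empty")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                             data = data.frame(time = surv$time,
                                               event = surv$event,
                                               group = group))
    sf <- survival::survfit(survival::Surv(time, event) ~ group,
                            data = data.frame(time = surv$time,
                                              event = surv$event,
                                              group = group))
    curves <- data.frame(
        group = rep(sub("^group=", "", names(sf$strata)),
                    times = sf$strata),
        time = sf$time, nRisk = sf$n.risk, nEvent = sf$n.event,
        surv = sf$surv, stringsAsFactors = FALSE)
    list(chiSquare = unname(sd$chisq),
         p = stats::pchisq(unname(sd$chisq), df = 1L, lower.tail = FALSE),
         groupSizes = table(group), curves = curves)
}
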