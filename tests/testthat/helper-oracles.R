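# Independent brute-force oracles. Each re-derives the quantity from its
# literal definition, without touching the package's implementation paths.

# Exhaustive running-sum scan over every rank k. `w` are the non-negative
# weights aligned with the descending-expression order, `vals` the values in
# that order; returns the deviation at the first k maximising |F - B|.
oracleRunningSum <- function(w, vals) {
    support <- w > 0
    m0 <- sum(!support)
    stopifnot(m0 > 0)
    S <- sum(w * abs(vals))
    F <- cumsum(w * abs(vals)) / S
    B <- cumsum(!support) / m0
    dev <- F - B
    dev[which.max(abs(dev))]
}

# Plug-in mutual information of a joint count table, in nats.
oraclePluginMI <- function(counts) {
    n <- sum(counts)
    p <- counts / n
    px <- rowSums(p)
    py <- colSums(p)
    mi <- 0
    for (i in seq_len(nrow(counts)))
        for (j in seq_len(ncol(counts)))
            if (p[i, j] > 0)
                mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    mi
}

# Exhaustive DPI: enumerate every node triple, apply the simultaneous
# removal rule against the input MI values.
oracleDPI <- function(edges, tolerance = 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mi <- setNames(edges$mi, key(edges$regulator, edges$target))
    nodes <- sort(unique(c(edges$regulator, edges$target)))
    drop <- character()
    if (length(nodes) >= 3) {
        cmb <- combn(nodes, 3)
        for (i in seq_len(ncol(cmb))) {
            v <- cmb[, i]
            k <- c(key(v[1], v[2]), key(v[1], v[3]), key(v[2], v[3]))
            if (!all(k %in% names(mi))) next
            m <- mi[k]
            weakest <- which.min(m)
            if (m[weakest] < (1 - tolerance) * min(m[-weakest]))
                drop <- c(drop, k[weakest])
        }
    }
    edges[!key(edges$regulator, edges$target) %in% drop, , drop = FALSE]
}

# Cox partial log-likelihood for a single covariate, no ties assumed
# (Breslow and Efron coincide); maximised by golden-section search.
oracleCoxBeta <- function(x, time, event, interval = c(-15, 15)) {
    stopifnot(!anyDuplicated(time[event == 1]))
    loglik <- function(b) {
        s <- 0
        for (i in which(event == 1)) {
            risk <- time >= time[i]
            s <- s + x[i] * b - log(sum(exp(x[risk] * b)))
        }
        s
    }
    stats::optimize(loglik, interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Literal two-group log-rank statistic (no tied event times across groups
# assumed not required; handles ties via the standard formula).
oracleLogrank <- function(time, event, group) {
    ev <- sort(unique(time[event == 1]))
    o1 <- e1 <- v <- 0
    for (t in ev) {
        n <- sum(time >= t)
        n1 <- sum(time >= t & group == levels(factor(group))[1])
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & group == levels(factor(group))[1])
        o1 <- o1 + d1
        e1 <- e1 + d * n1 / n
        if (n > 1)
            v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (o1 - e1)^2 / v
}

# Literal step-up Benjamini-Hochberg.
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- 1
    for (i in m:1) {
        running <- min(running, p[o[i]] * m / i)
        adj[o[i]] <- running
    }
    adj
}

oracleStouffer <- function(z, w) sum(w * z) / sqrt(sum(w^2))

# Upper hypergeometric tail by explicit enumeration over the top-left cell.
oracleFisherUpper <- function(a, b, c, d) {
    n <- a + b + c + d
    kmax <- min(a + b, a + c)
    k <- a:kmax
    sum(exp(lchoose(a + b, k) + lchoose(c + d, a + c - k) -
                lchoose(n, a + c)))
}

# O(n^3) complete-linkage agglomeration; returns the merge heights and the
# two-cluster partition.
oracleCompleteLinkage <- function(mat) {
    d <- as.matrix(dist(mat))
    clusters <- as.list(seq_len(nrow(mat)))
    heights <- numeric()
    while (length(clusters) > 1) {
        best <- c(Inf, NA, NA)
        for (i in seq_along(clusters))
            for (j in seq_along(clusters))
                if (i < j) {
                    h <- max(d[clusters[[i]], clusters[[j]]])
                    if (h < best[1]) best <- c(h, i, j)
                }
        heights <- c(heights, best[1])
        clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
        clusters[[best[3]]] <- NULL
        if (length(clusters) == 2) twoCut <- clusters
    }
    list(heights = heights, twoCut = twoCut)
}

# Literal per-patient CNA contingency construction (interval arithmetic done
# by hand on start/end vectors, independent of GenomicRanges).
oraclePatientCnaTable <- function(hazardous, protective, ivDf, segDf,
                                  callWanted) {
    prog <- c(hazardous, protective)
    isHaz <- prog %in% hazardous
    altered <- vapply(prog, function(g) {
        gi <- ivDf[ivDf$gene == g, ]
        any(segDf$call == callWanted & segDf$chrom == gi$chrom &
                segDf$start <= gi$end & segDf$end >= gi$start)
    }, logical(1))
    first <- if (callWanted == 1L) isHaz else !isHaz
    matrix(c(sum(first & altered), sum(first & !altered),
             sum(!first & altered), sum(!first & !altered)),
           2, 2, byrow = TRUE)
}
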