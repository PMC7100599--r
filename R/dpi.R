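# Data processing inequality pruning.

#' Prune indirect edges with the data processing inequality
#'
#' In every fully connected triple of the input network the edge with the
#' smallest mutual information is presumed indirect and removed when its MI
#' falls below \code{(1 - tolerance)} times the smaller of the other two.
#' All removal decisions are evaluated against the input network and applied
#' simultaneously, so the result does not depend on triangle order.
#'
#' @param network an \linkS4class{MINetwork}.
#' @param tolerance fraction in [0, 1); 0 applies the strict inequality.
#' @return The pruned \linkS4class{MINetwork}; the edge set is always a
#'   subset of the input edge set.
#' @export
applyDPI <- function(network, tolerance = 0) {
    stopifnot(is(network, "MINetwork"))
    if (tolerance < 0 || tolerance >= 1)
        stop("tolerance must lie in [0, 1)")
    e <- network@edges
    if (nrow(e) < 3L) return(network)
    # undirected edge keys
    a <- pmin(e$regulator, e$target)
    b <- pmax(e$regulator, e$target)
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (undirected) edges in network")
    g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
    tri <- igraph::triangles(g)
    if (length(tri) == 0L) return(network)
    vn <- igraph::V(g)$name
    tri <- matrix(vn[as.integer(tri)], ncol = 3L, byrow = TRUE)
    mi <- stats::setNames(e$mi, key)
    drop <- logical(nrow(e))
    names(drop) <- key
    for (i in seq_len(nrow(tri))) {
        v <- tri[i, ]
        k <- c(paste(min(v[1], v[2]), max(v[1], v[2]), sep = "\r"),
               paste(min(v[1], v[3]), max(v[1], v[3]), sep = "\r"),
               paste(min(v[2], v[3]), max(v[2], v[3]), sep = "\r"))
        m <- mi[k]
        weakest <- which.min(m)
        others <- m[-weakest]
        if (m[weakest] < (1 - tolerance) * min(others))
            drop[k[weakest]] <- TRUE
    }
    MINetwork(e[!drop[key], , drop = FALSE], network@nBootstrap)
}
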