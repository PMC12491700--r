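## Random walk with restart over the interaction network and assembly of the
## gene x predictor affinity matrix.

#' Normalised adjacency operator of a weighted network
#'
#' \code{symmetric} gives \eqn{D^{-1/2} W D^{-1/2}} (the normalised-Laplacian
#' style operator), \code{column} the column-stochastic \eqn{W D^{-1}} and
#' \code{row} the row-stochastic \eqn{D^{-1} W}.  Isolated nodes get zero
#' rows/columns.
#'
#' @param network undirected weighted igraph (weights > 0, no self-loops).
#' @param method normalisation scheme.
#' @return dense numeric matrix with node names on both dimensions.
#' @export
normaliseAdjacency <- function(network,
                               method = c("symmetric", "column", "row")) {
    method <- match.arg(method)
    if (igraph::vcount(network) == 0) stop("empty network")
    w <- igraph::E(network)$weight
    if (is.null(w)) igraph::E(network)$weight <- 1
    W <- igraph::as_adjacency_matrix(network, attr = "weight", sparse = FALSE)
    d <- rowSums(W)
    inv <- ifelse(d > 0, 1 / d, 0)
    A <- switch(method,
        symmetric = {
            s <- sqrt(inv)
            t(W * s) * s        # D^-1/2 W D^-1/2 (W symmetric)
        },
        column = t(t(W) * inv), # W D^-1: columns sum to 1
        row = W * inv)          # D^-1 W: rows sum to 1
    dimnames(A) <- list(igraph::V(network)$name, igraph::V(network)$name)
    A
}

#' Random walk with restart
#'
#' Iterates \eqn{p_{t+1} = (1-\gamma) A p_t + \gamma p_0} to the steady state,
#' where \eqn{p_0} holds the (normalised) seed gene scores and \eqn{\gamma}
#' is the restart probability.  The fixed point solves
#' \eqn{(I - (1-\gamma)A) p = \gamma p_0}.
#'
#' @param network undirected weighted igraph.
#' @param seeds named numeric vector of non-negative seed scores; names are
#'   gene ids.  Seeds absent from the network are ignored; at least one must
#'   remain.
#' @param gamma restart probability in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @param method adjacency normalisation (see
#'   \code{\link{normaliseAdjacency}}).
#' @return named numeric affinity vector over all network nodes; exactly the
#'   nodes reachable from a seed are positive.
#' @export
rwr <- function(network, seeds, gamma = 0.3, tol = 1e-6, max_iter = 10000L,
                method = "symmetric") {
    if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
    if (any(seeds < 0)) stop("seed scores must be non-negative")
    A <- normaliseAdjacency(network, method)
    nodes <- rownames(A)
    p0 <- setNames(numeric(length(nodes)), nodes)
    keep <- intersect(names(seeds)[seeds > 0], nodes)
    if (length(keep) == 0) stop("no seeds on network")
    p0[keep] <- seeds[keep]
    p0 <- p0 / sum(p0)
    p <- p0
    for (it in seq_len(max_iter)) {
        p_new <- (1 - gamma) * drop(A %*% p) + gamma * p0
        delta <- sum(abs(p_new - p))
        p <- p_new
        if (delta < tol) break
    }
    setNames(drop(p), nodes)
}

#' Assemble the gene-by-predictor affinity matrix
#'
#' Runs one restart walk per predictor from that predictor's seed gene
#' scores, aligns all walks on the full node universe and rescales every
#' column to sum to one, giving per-predictor relative affinities in [0, 1].
#' Seed provenance is recorded per cell.
#'
#' @param network undirected weighted igraph.
#' @param seed_lists named list: one named numeric score vector (or a
#'   data.frame with \code{gene_id} and \code{score} columns) per predictor.
#' @param gamma restart probability.
#' @param method adjacency normalisation.
#' @param tol,max_iter passed to \code{\link{rwr}}.
#' @return a \linkS4class{PredictorMatrix}.
#' @export
buildPredictorMatrix <- function(network, seed_lists, gamma = 0.3,
                                 method = "symmetric", tol = 1e-6,
                                 max_iter = 10000L) {
    if (length(seed_lists) == 0) stop("at least one predictor required")
    if (is.null(names(seed_lists)) || any(!nzchar(names(seed_lists))))
        stop("seed_lists must be named by predictor")
    as_scores <- function(x) {
        if (is.data.frame(x)) setNames(x$score, x$gene_id) else x
    }
    nodes <- igraph::V(network)$name
    cols <- lapply(seed_lists, function(sl) {
        rwr(network, as_scores(sl), gamma = gamma, tol = tol,
            max_iter = max_iter, method = method)[nodes]
    })
    af <- do.call(cbind, cols)
    af <- sweep(af, 2, colSums(af), "/")
    rownames(af) <- nodes
    seeded <- vapply(seed_lists, function(sl) {
        s <- as_scores(sl)
        nodes %in% names(s)[s > 0]
    }, logical(length(nodes)))
    if (is.null(dim(seeded))) seeded <- matrix(seeded, nrow = length(nodes))
    dimnames(seeded) <- dimnames(af)
    new("PredictorMatrix", affinity = af, seeded = seeded,
        gamma = as.numeric(gamma))
}
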