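## Pathway-crosstalk discovery: prize-collecting Steiner tree heuristic
## (minimum-spanning scaffold + strong pruning), desired-size search by
## bisection on the cost scale, degree-preserving permutation significance,
## and the pathway-centric maximum-spanning-tree view.

#' Build a prize graph from a network and priority ratings
#'
#' Node prizes are the 0-10 priority ratings restricted to graph nodes
#' (genes absent from the ranking get prize 0); edge costs default to
#' \code{1 - weight/max(weight)}, floored at \code{cost_floor}, so stronger
#' interactions are cheaper to keep.
#'
#' @param network undirected weighted igraph.
#' @param prizes named numeric vector (e.g. \code{ratings(pt)}).
#' @param cost_floor minimum edge cost.
#' @return igraph with vertex attribute \code{prize} and edge attribute
#'   \code{cost}.
#' @export
makePrizeGraph <- function(network, prizes, cost_floor = 0.01) {
    g <- network
    w <- igraph::E(g)$weight
    if (is.null(w)) w <- rep(1, igraph::ecount(g))
    igraph::E(g)$cost <- pmax(cost_floor, 1 - w / max(w))
    pz <- setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
    common <- intersect(names(prizes), names(pz))
    pz[common] <- prizes[common]
    if (any(pz < 0)) stop("prizes must be non-negative")
    igraph::V(g)$prize <- unname(pz)
    g
}

## Internal solver architecture: everything that depends only on the graph
## topology and edge costs (dense cost matrices, the cost-MST as parent
## arrays) is computed once by .pcst_prep(); each evaluation for a given
## prize vector and cost scale is then pure array work, which keeps the
## bisection search and the permutation test fast.

## Strong pruning with rerooting on a tree given as parent arrays: for every
## node the net worth of the best pruned subtree rooted there is computed in
## O(n) by a downward pass (child side) and an upward pass (parent side);
## the best subtree over all roots is reconstructed with its edges.
.prune_arrays <- function(parent, cost_up, ord, prize, lambda,
                          need_kept = TRUE) {
    n <- length(prize)
    if (n == 1) {
        return(list(value = prize[1], kept = 1L,
                    edges = matrix(numeric(0), 0, 3)))
    }
    down <- prize                  # best subtree value hanging below v
    contrib <- numeric(n)          # v's clipped contribution to its parent
    for (v in rev(ord)) {
        p <- parent[v]
        if (!is.na(p)) {
            contrib[v] <- max(0, down[v] - lambda * cost_up[v])
            down[p] <- down[p] + contrib[v]
        }
    }
    upA <- numeric(n)              # best subtree on the parent side of v
    up_contrib <- numeric(n)
    for (v in ord) {
        p <- parent[v]
        if (is.na(p)) next
        upA[v] <- down[p] - contrib[v] +
            if (!is.na(parent[p])) up_contrib[p] else 0
        up_contrib[v] <- max(0, upA[v] - lambda * cost_up[v])
    }
    best_val <- down + up_contrib
    root_star <- which.max(best_val)
    if (!need_kept)
        return(list(value = best_val[root_star], kept = NULL, edges = NULL))

    nonroot <- ord[!is.na(parent[ord])]
    children <- split(nonroot, parent[nonroot])
    kept <- integer(0)
    edges <- matrix(numeric(0), 0, 3)   # (a, b, cost)
    stack <- list(c(root_star, NA_integer_))    # (node, arrived-from)
    while (length(stack) > 0) {
        top <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        v <- top[1]; from <- top[2]
        kept <- c(kept, v)
        for (w in children[[as.character(v)]]) {
            if (!is.na(from) && w == from) next
            if (contrib[w] > 0) {
                stack <- c(stack, list(c(w, v)))
                edges <- rbind(edges, c(v, w, cost_up[w]))
            }
        }
        p <- parent[v]
        if (!is.na(p) && (is.na(from) || p != from) && up_contrib[v] > 0) {
            stack <- c(stack, list(c(p, v)))
            edges <- rbind(edges, c(v, p, cost_up[v]))
        }
    }
    list(value = best_val[root_star], kept = sort(kept), edges = edges)
}

## Prize-biased Prim spanning tree: attachment order lambda*cost - prize,
## so cheap routes towards high-prize nodes enter the scaffold even when
## the pure-cost MST would bypass them.  Returns parent arrays.
.biased_prim <- function(C, prize, lambda, start) {
    n <- nrow(C)
    in_tree <- rep(FALSE, n); in_tree[start] <- TRUE
    key <- lambda * C[start, ] - prize
    conn_cost <- C[start, ]
    parent <- rep(start, n)
    parent[start] <- NA_integer_
    ord <- integer(n); ord[1] <- start
    for (step in seq_len(n - 1L)) {
        key_masked <- ifelse(in_tree, Inf, key)
        v <- which.min(key_masked)
        in_tree[v] <- TRUE
        ord[step + 1L] <- v
        upd <- !in_tree & C[v, ] < conn_cost
        conn_cost[upd] <- C[v, upd]
        key[upd] <- lambda * C[v, upd] - prize[upd]
        parent[upd] <- v
    }
    list(parent = parent, cost_up = conn_cost, ord = ord)
}

## One-off preparation: per connected component, the dense cost matrix and
## the cost-MST as parent arrays (both independent of prizes and lambda).
.pcst_prep <- function(graph) {
    comps <- igraph::components(graph)
    prep <- vector("list", comps$no)
    for (ci in seq_len(comps$no)) {
        idx <- which(comps$membership == ci)
        sub <- igraph::induced_subgraph(graph, idx)
        n <- length(idx)
        if (n == 1) {
            prep[[ci]] <- list(idx = idx, n = 1L)
            next
        }
        C <- igraph::as_adjacency_matrix(sub, attr = "cost", sparse = FALSE)
        C[C == 0] <- Inf
        mst <- igraph::mst(sub, weights = igraph::E(sub)$cost)
        d <- igraph::dfs(mst, root = 1, father = TRUE)
        ord <- as.integer(d$order)
        parent <- as.integer(d$father)
        cost_up <- rep(NA_real_, n)
        nonroot <- ord[-1]
        eids <- igraph::get_edge_ids(mst,
            as.vector(rbind(parent[nonroot], nonroot)))
        cost_up[nonroot] <- igraph::E(mst)$cost[eids]
        prep[[ci]] <- list(idx = idx, n = n, C = C,
                           min_cost = apply(C, 1, function(r)
                               min(r[is.finite(r)])),
                           mst = list(parent = parent, cost_up = cost_up,
                                      ord = ord))
    }
    prep
}

## Evaluate the heuristic for a prize vector (global order) at scale lambda.
## Returns the best value, the kept global indices and kept edges
## (global index pairs with costs).
.pcst_eval <- function(prep, prize_all, lambda, need_kept = TRUE) {
    best <- NULL
    for (comp in prep) {
        pz <- prize_all[comp$idx]
        if (comp$n == 1) {
            cand <- list(list(value = pz, kept = 1L,
                              edges = matrix(numeric(0), 0, 3)))
        } else {
            cand <- list(with(comp$mst,
                .prune_arrays(parent, cost_up, ord, pz, lambda, need_kept)))
            if (comp$n >= 3) {
                starts <- unique(c(which.max(pz),
                    which.max(pz - lambda * comp$min_cost)))
                for (st in starts) {
                    pr <- .biased_prim(comp$C, pz, lambda, st)
                    cand <- c(cand, list(.prune_arrays(pr$parent,
                        pr$cost_up, pr$ord, pz, lambda, need_kept)))
                }
            }
        }
        for (r in cand) {
            if (is.null(best) || r$value > best$value)
                best <- list(value = r$value,
                             kept = if (need_kept) comp$idx[r$kept],
                             edges = if (need_kept && nrow(r$edges) > 0)
                                 cbind(comp$idx[r$edges[, 1]],
                                       comp$idx[r$edges[, 2]],
                                       r$edges[, 3])
                                 else matrix(numeric(0), 0, 3))
        }
    }
    best
}

## Size-targeted search on a prepared graph: bisection on lambda (tree size
## is non-increasing in lambda), keeping the closest achievable size with
## ties to the larger value.
.pcst_size_search <- function(prep, prize_all, target_n,
                              lambda_range = c(1e-4, 1e4), max_iter = 60L,
                              need_kept = TRUE) {
    lo <- lambda_range[1]; hi <- lambda_range[2]
    best <- NULL
    consider <- function(res, best) {
        if (is.null(best)) return(res)
        d_new <- abs(length(res$kept) - target_n)
        d_old <- abs(length(best$kept) - target_n)
        if (d_new < d_old || (d_new == d_old && res$value > best$value))
            res else best
    }
    r <- .pcst_eval(prep, prize_all, lo, TRUE); r$lambda <- lo
    best <- consider(r, best)
    r <- .pcst_eval(prep, prize_all, hi, TRUE); r$lambda <- hi
    best <- consider(r, best)
    for (i in seq_len(max_iter)) {
        if (length(best$kept) == target_n) break
        mid <- sqrt(lo * hi)
        r <- .pcst_eval(prep, prize_all, mid, TRUE); r$lambda <- mid
        best <- consider(r, best)
        if (length(r$kept) > target_n) lo <- mid else hi <- mid
        if (hi / lo < 1 + 1e-9) break
    }
    best
}

## Assemble a CrosstalkResult from an evaluation on the original graph.
.pcst_result <- function(graph, ev, lambda, target_n = NA_real_) {
    names_all <- igraph::V(graph)$name
    prize_all <- igraph::V(graph)$prize
    nodes <- names_all[ev$kept]
    edges <- if (nrow(ev$edges) > 0)
        data.frame(from = names_all[ev$edges[, 1]],
                   to = names_all[ev$edges[, 2]],
                   cost = ev$edges[, 3], stringsAsFactors = FALSE)
    else data.frame(from = character(0), to = character(0),
                    cost = numeric(0), stringsAsFactors = FALSE)
    prizes <- setNames(prize_all[ev$kept], nodes)
    new("CrosstalkResult", nodes = nodes, edges = edges, prizes = prizes,
        objective = sum(prizes) - lambda * sum(edges$cost),
        lambda = lambda, pvalue = NA_real_, target_n = target_n)
}

#' Prize-collecting Steiner tree heuristic
#'
#' Finds a connected acyclic subnetwork maximising total node prize minus
#' \code{lambda} times total edge cost.  The heuristic builds a minimum
#' spanning scaffold on the (cost-weighted) edges of each connected
#' component, then strong-prunes it from every possible root, keeping the
#' best net-worth subtree across roots and components.  The objective is
#' never below the best single node's prize (a singleton tree is always
#' admissible).
#'
#' @param graph igraph with \code{prize} vertex and \code{cost} edge
#'   attributes (see \code{\link{makePrizeGraph}}).
#' @param lambda positive scale on edge costs.
#' @return a \linkS4class{CrosstalkResult} (permutation P not yet set).
#' @export
pcst <- function(graph, lambda = 1) {
    if (lambda <= 0) stop("lambda must be > 0")
    prize_all <- igraph::V(graph)$prize
    if (is.null(prize_all)) stop("graph has no prize attribute")
    if (all(prize_all == 0))
        warning("all prizes are 0; returning the best singleton")
    ev <- .pcst_eval(.pcst_prep(graph), prize_all, lambda)
    .pcst_result(graph, ev, lambda)
}

#' Prize-collecting tree of a desired node count
#'
#' Larger cost scales shrink the selected tree; the requested size is found
#' by bisection on \code{lambda}, keeping the closest achievable size (ties
#' to the larger objective) when the exact count is unattainable.
#'
#' @param graph prize graph.
#' @param target_n desired node count (1..|V|).
#' @param lambda_range initial bracket for the search.
#' @param max_iter bisection iterations.
#' @return a \linkS4class{CrosstalkResult} with \code{target_n} recorded.
#' @export
pcstWithSize <- function(graph, target_n, lambda_range = c(1e-4, 1e4),
                         max_iter = 60L) {
    nv <- igraph::vcount(graph)
    if (target_n < 1 || target_n > nv)
        stop("target_n must be in 1..|V|")
    prize_all <- igraph::V(graph)$prize
    if (is.null(prize_all)) stop("graph has no prize attribute")
    best <- .pcst_size_search(.pcst_prep(graph), prize_all, target_n,
                              lambda_range, max_iter)
    if (length(best$kept) != target_n)
        warning("target size ", target_n, " unreachable; returning ",
                length(best$kept), " nodes")
    .pcst_result(graph, best, best$lambda, as.numeric(target_n))
}

#' Degree-preserving permutation test of a crosstalk
#'
#' Node prizes are shuffled within degree bins (quantile bins on degree;
#' bins with fewer than 2 nodes are merged with their neighbour) and the
#' tree search is re-run with identical settings (same \code{lambda}, or
#' the same desired size when the observed result used one).  The P-value is
#' \eqn{(1 + \#\{perm \ge obs\})/(1 + n_{perm})} on the chosen statistic.
#'
#' @param graph prize graph.
#' @param result observed \linkS4class{CrosstalkResult}.
#' @param n_perm number of permutations (default 100).
#' @param n_degree_bins quantile bins on degree (default 10).
#' @param seed integer RNG seed.
#' @param statistic \code{"objective"} (default) or \code{"prize"} (summed
#'   prize of the selected nodes).
#' @return the result with \code{pvalue} set.
#' @export
permutationTest <- function(graph, result, n_perm = 100L,
                            n_degree_bins = 10L, seed = 1L,
                            statistic = c("objective", "prize")) {
    statistic <- match.arg(statistic)
    if (n_perm < 1) stop("n_perm must be >= 1")
    set.seed(as.integer(seed))
    deg <- igraph::degree(graph)
    qs <- unique(quantile(deg, probs = seq(0, 1,
        length.out = n_degree_bins + 1L)))
    bins <- cut(deg, breaks = qs, include.lowest = TRUE, labels = FALSE)
    ## merge undersized bins upward
    repeat {
        tab <- table(bins)
        small <- as.integer(names(tab)[tab < 2])
        if (length(small) == 0 || length(tab) == 1) break
        s <- small[1]
        neigh <- if (any(bins > s)) min(bins[bins > s]) else max(bins[bins < s])
        bins[bins == s] <- neigh
    }
    obs <- if (statistic == "objective") result@objective
           else sum(result@prizes)
    prep <- .pcst_prep(graph)
    prize0 <- igraph::V(graph)$prize
    stat_of <- function(ev) {
        if (statistic == "objective") ev$value
        else sum(ev$prize_perm[ev$kept])
    }
    hits <- 0L
    for (b in seq_len(n_perm)) {
        perm <- prize0
        for (bin in unique(bins)) {
            idx <- which(bins == bin)
            perm[idx] <- prize0[sample(idx)]
        }
        ev <- if (!is.na(result@target_n))
            .pcst_size_search(prep, perm, result@target_n)
        else .pcst_eval(prep, perm, result@lambda)
        ev$prize_perm <- perm
        if (stat_of(ev) >= obs - 1e-12) hits <- hits + 1L
    }
    result@pvalue <- (1 + hits) / (1 + n_perm)
    result
}

#' Pathway-centric view of a crosstalk
#'
#' Pathways significantly over-represented among the crosstalk genes
#' (one-sided Fisher test at the configured threshold) become nodes sized by
#' their in-crosstalk member count; pathway pairs are joined by edges
#' weighted by shared crosstalk members, of which only the maximum-weight
#' spanning forest is retained.
#'
#' @param result a \linkS4class{CrosstalkResult}.
#' @param gene_sets named list of pathway gene sets.
#' @param universe background gene universe.
#' @param alpha significance threshold.
#' @param by \code{"fdr"} (default) or \code{"p"}.
#' @return list: \code{nodes} (pathway, size, p, fdr), \code{edges}
#'   (from, to, shared), \code{enrichment} (full table).
#' @export
pathwayView <- function(result, gene_sets, universe, alpha = 0.05,
                        by = c("fdr", "p")) {
    by <- match.arg(by)
    genes <- crosstalkGenes(result)
    enr <- setEnrichment(genes, gene_sets, universe)
    sig <- enr[enr[[by]] < alpha, , drop = FALSE]
    if (nrow(sig) == 0) {
        warning("no significant pathway at ", by, " < ", alpha)
        return(list(nodes = data.frame(pathway = character(0),
                                       size = integer(0), p = numeric(0),
                                       fdr = numeric(0)),
                    edges = data.frame(from = character(0),
                                       to = character(0),
                                       shared = integer(0)),
                    enrichment = enr))
    }
    members <- lapply(sig$set, function(nm)
        intersect(gene_sets[[nm]], genes))
    names(members) <- sig$set
    nodes <- data.frame(pathway = sig$set,
                        size = lengths(members),
                        p = sig$p, fdr = sig$fdr, stringsAsFactors = FALSE)
    edges <- data.frame(from = character(0), to = character(0),
                        shared = integer(0), stringsAsFactors = FALSE)
    if (nrow(sig) >= 2) {
        pairs <- t(combn(sig$set, 2))
        shared <- vapply(seq_len(nrow(pairs)), function(i)
            length(intersect(members[[pairs[i, 1]]],
                             members[[pairs[i, 2]]])), integer(1))
        keep <- shared > 0
        if (any(keep)) {
            pg <- igraph::graph_from_data_frame(
                data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                           weight = shared[keep]),
                directed = FALSE, vertices = sig$set)
            ## maximum-weight spanning forest = MST on negated weights
            mstg <- igraph::mst(pg, weights = -igraph::E(pg)$weight)
            el <- igraph::as_edgelist(mstg)
            edges <- data.frame(from = el[, 1], to = el[, 2],
                                shared = as.integer(igraph::E(mstg)$weight),
                                stringsAsFactors = FALSE)
        }
    }
    list(nodes = nodes, edges = edges, enrichment = enr)
}
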