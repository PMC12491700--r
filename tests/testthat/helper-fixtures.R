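## Shared fixtures, built in code at test time.

## tiny weighted graph with named nodes
tiny_graph <- function(edges, weights = rep(1, nrow(edges))) {
    g <- igraph::graph_from_data_frame(
        data.frame(from = edges[, 1], to = edges[, 2], weight = weights),
        directed = FALSE)
    g
}

## write a GWAS TSV and return its path
write_gwas_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

gwas_row <- function(snp_id, pos, p_value, lead_id = snp_id, r2 = 1,
                     chrom = "chr1") {
    data.frame(snp_id = snp_id, chrom = chrom, pos = pos, p_value = p_value,
               lead_id = lead_id, r2 = r2, stringsAsFactors = FALSE)
}

## exact PCST optimum by enumeration over connected node subsets: for a
## fixed subset the optimal connector is its induced MST (Prim on the dense
## cost matrix; an unreachable node marks the subset disconnected).
brute_pcst <- function(g, lambda) {
    n <- igraph::vcount(g)
    C <- igraph::as_adjacency_matrix(g, attr = "cost", sparse = FALSE)
    C[C == 0] <- Inf
    prize <- igraph::V(g)$prize
    best <- 0
    pow <- 2^(0:(n - 1))
    for (mask in 1:(2^n - 1)) {
        S <- which(bitwAnd(mask, pow) > 0)
        if (length(S) == 1) {
            best <- max(best, prize[S])
            next
        }
        sub <- C[S, S, drop = FALSE]
        nS <- length(S)
        intree <- c(TRUE, rep(FALSE, nS - 1))
        key <- sub[1, ]
        cost_tot <- 0
        for (step in 2:nS) {
            key[intree] <- Inf
            v <- which.min(key)
            if (!is.finite(key[v])) { cost_tot <- Inf; break }
            intree[v] <- TRUE
            cost_tot <- cost_tot + key[v]
            key <- pmin(key, sub[v, ])
        }
        if (is.finite(cost_tot))
            best <- max(best, sum(prize[S]) - lambda * cost_tot)
    }
    best
}

## random prize graph for oracle comparisons
random_prize_graph <- function(n, seed) {
    set.seed(seed)
    repeat {
        g <- igraph::sample_gnp(n, 0.4)
        if (igraph::ecount(g) > 0) break
    }
    igraph::V(g)$name <- paste0("v", seq_len(n))
    igraph::V(g)$prize <- runif(n, 0, 5)
    igraph::E(g)$cost <- runif(igraph::ecount(g), 0.1, 2)
    g
}

## exhaustive hypergeometric upper tail P(X >= k)
brute_hyper_tail <- function(k, K, N, n) {
    sum(vapply(k:min(K, n), function(i)
        choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

## two 5-cliques joined by a single bridge edge
two_clique_graph <- function() {
    g <- igraph::disjoint_union(igraph::make_full_graph(5),
                                igraph::make_full_graph(5))
    g <- igraph::add_edges(g, c(1, 6))
    igraph::V(g)$name <- paste0("n", 1:10)
    g
}

## exhaustive minimum of the RB Hamiltonian over all 2-partitions
brute_best_bipartition <- function(g, gamma_rb = 1) {
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    k <- rowSums(A)
    two_m <- sum(k)
    n <- nrow(A)
    ham <- function(lab) {
        H <- 0
        for (c in unique(lab)) {
            idx <- which(lab == c)
            if (length(idx) < 2) next
            H <- H - (sum(A[idx, idx])) / 2 +
                gamma_rb * (sum(k[idx])^2 - sum(k[idx]^2)) / (2 * two_m)
        }
        H
    }
    best <- Inf; best_lab <- NULL
    for (mask in 0:(2^(n - 1) - 1)) {
        lab <- c(1L, as.integer(bitwAnd(mask, 2^(0:(n - 2))) > 0) + 1L)
        h <- ham(lab)
        if (h < best) { best <- h; best_lab <- lab }
    }
    list(H = best, labels = best_lab)
}
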