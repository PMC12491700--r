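## Crosstalk follow-ups: effect-by-removal robustness, drug-repurposing
## enrichment, and spin-glass modular decomposition with per-module
## therapeutic enrichment.

#' Effect of removing a node set from a network
#'
#' Deletes the nodes and their incident edges and reports the disconnected
#' fraction \eqn{1 - |largest remaining component| / |V_{original}|} (a
#' removed node counts as disconnected, so removing everything gives 1).
#'
#' @param network igraph.
#' @param remove character vector of node names (may be empty).
#' @return list (class \code{RemovalReport}): \code{removed},
#'   \code{fraction}, \code{disconnected} (removed nodes plus nodes outside
#'   the largest remaining component).
#' @export
removalEffect <- function(network, remove = character(0)) {
    vn <- igraph::V(network)$name
    if (!all(remove %in% vn)) stop("remove must be a subset of the nodes")
    n0 <- length(vn)
    if (length(remove) == n0) {
        warning("removing every node disconnects the whole network")
        return(structure(list(removed = remove, fraction = 1,
                              disconnected = vn), class = "RemovalReport"))
    }
    g2 <- igraph::delete_vertices(network, remove)
    comps <- igraph::components(g2)
    largest <- which.max(comps$csize)
    inside <- igraph::V(g2)$name[comps$membership == largest]
    structure(list(removed = remove,
                   fraction = 1 - max(comps$csize) / n0,
                   disconnected = sort(setdiff(vn, inside))),
              class = "RemovalReport")
}

#' @export
print.RemovalReport <- function(x, ...) {
    cat(sprintf("RemovalReport: {%s} -> %.1f%% disconnected\n",
                paste(x$removed, collapse = ", "), 100 * x$fraction))
    invisible(x)
}

#' Exhaustive combinatorial node-removal analysis
#'
#' Evaluates the disconnected fraction for every subset of the candidate
#' nodes up to size \code{k_max}, ranked by fraction (descending), ties by
#' smaller set then lexicographically.  Refuses more than 1e6 subsets.
#'
#' @param network igraph.
#' @param k_max largest combination size.
#' @param candidates candidate nodes (default: all).
#' @return list: \code{report} (data.frame \code{combo}, \code{k},
#'   \code{fraction}, \code{rank}) and \code{incidence} (upset-style
#'   membership table, one logical column per candidate).
#' @export
combinatorialRemoval <- function(network, k_max = 2L,
                                 candidates = igraph::V(network)$name) {
    if (k_max < 1) stop("k_max must be >= 1")
    if (!all(candidates %in% igraph::V(network)$name))
        stop("candidates must be network nodes")
    nc <- length(candidates)
    total <- sum(choose(nc, seq_len(min(k_max, nc))))
    if (total > 1e6)
        stop("combinatorial blow-up (", total,
             " subsets); restrict candidates or lower k_max")
    candidates <- sort(candidates)
    combos <- list()
    for (k in seq_len(min(k_max, nc)))
        combos <- c(combos, combn(candidates, k, simplify = FALSE))
    frac <- vapply(combos, function(s)
        removalEffect(network, s)$fraction, numeric(1))
    combo_str <- vapply(combos, paste, character(1), collapse = ",")
    kk <- lengths(combos)
    ord <- order(-frac, kk, combo_str)
    report <- data.frame(combo = combo_str[ord], k = kk[ord],
                         fraction = frac[ord],
                         rank = seq_along(ord), stringsAsFactors = FALSE)
    incidence <- as.data.frame(do.call(rbind, lapply(combos[ord],
        function(s) candidates %in% s)))
    names(incidence) <- candidates
    incidence <- cbind(report["combo"], incidence)
    list(report = report, incidence = incidence)
}

#' Drug-repurposing enrichment of crosstalk genes
#'
#' Tests over-representation of approved-drug targets among the crosstalk
#' genes (2x2 table over the universe, one-sided hypergeometric), and emits
#' the gene-to-indication incidence list connecting crosstalk genes to the
#' approved drugs that already target them.
#'
#' @param crosstalk_genes character vector (subset of the universe).
#' @param drug_table data.frame from \code{\link{readDrugTable}}.
#' @param universe background gene universe.
#' @return list: \code{enrichment} (single-row table as
#'   \code{\link{setEnrichment}}) and \code{indications} (gene, drug,
#'   indication rows for crosstalk genes with approved drugs).
#' @export
drugEnrichment <- function(crosstalk_genes, drug_table, universe) {
    approved <- unique(drug_table$target[drug_table$approved])
    if (length(intersect(approved, universe)) == 0)
        stop("no approved drug target in the universe")
    enr <- setEnrichment(crosstalk_genes,
                         list(approved_drug_targets = approved), universe)
    hit <- drug_table$approved & drug_table$target %in% crosstalk_genes
    ind <- drug_table[hit, c("target", "drug", "indication")]
    names(ind)[1] <- "gene"
    rownames(ind) <- NULL
    list(enrichment = enr, indications = ind)
}

## Reichardt-Bornholdt Hamiltonian of a labelling:
## H = -sum_{i<j} (A_ij - gamma k_i k_j / 2m) delta(s_i, s_j)
.rb_hamiltonian <- function(A, k, two_m, gamma_rb, labels) {
    H <- 0
    for (c in unique(labels)) {
        idx <- which(labels == c)
        if (length(idx) < 2) next
        Asub <- A[idx, idx]
        H <- H - (sum(Asub) - sum(diag(Asub))) / 2 +
            gamma_rb * (sum(k[idx])^2 - sum(k[idx]^2)) / (2 * two_m)
    }
    H
}

#' Spin-glass modular decomposition by simulated annealing
#'
#' Minimises the Reichardt-Bornholdt Potts Hamiltonian
#' \deqn{H = -\sum_{i<j} (A_{ij} - \gamma p_{ij})\, \delta(\sigma_i,\sigma_j)}
#' with the configuration-model null \eqn{p_{ij} = k_i k_j / 2m}, by seeded
#' single-spin-flip simulated annealing (geometric cooling, restarts keep
#' the best).  At \eqn{\gamma = 1} the minimum corresponds to the maximum
#' modularity partition.  Disconnected networks are decomposed per
#' component.
#'
#' @param network igraph (edge weights used if present).
#' @param gamma_rb resolution parameter (default 1).
#' @param t0 initial temperature.
#' @param cooling geometric cooling factor per sweep.
#' @param sweeps number of sweeps per restart.
#' @param restarts number of annealing restarts.
#' @param seed integer RNG seed.
#' @param q_max maximum number of spin states.
#' @return list (class \code{ModulePartition}): \code{membership} (named,
#'   modules numbered by size, largest first), \code{labels}
#'   ("PM1"..), \code{hamiltonian}, \code{trace} (per-restart final H and
#'   acceptance rate, plus the temperature ladder).
#' @export
spinglassModules <- function(network, gamma_rb = 1, t0 = 1, cooling = 0.99,
                             sweeps = 200L, restarts = 20L, seed = 1L,
                             q_max = NULL) {
    n_all <- igraph::vcount(network)
    if (n_all == 0) stop("empty graph")
    set.seed(as.integer(seed))
    comps <- igraph::components(network)
    membership <- setNames(integer(n_all), igraph::V(network)$name)
    offset <- 0L
    trace <- list(temperatures = t0 * cooling^(seq_len(sweeps) - 1),
                  restarts = data.frame())
    for (ci in seq_len(comps$no)) {
        sub <- igraph::induced_subgraph(network, which(comps$membership == ci))
        n <- igraph::vcount(sub)
        if (n == 1) {
            membership[igraph::V(sub)$name] <- offset + 1L
            offset <- offset + 1L
            next
        }
        has_w <- !is.null(igraph::E(sub)$weight)
        A <- igraph::as_adjacency_matrix(sub, sparse = FALSE,
            attr = if (has_w) "weight" else NULL)
        k <- rowSums(A)
        two_m <- sum(k)
        q <- if (is.null(q_max)) min(n, 20L) else min(q_max, n)
        best_lab <- NULL; best_H <- Inf
        for (r in seq_len(restarts)) {
            lab <- sample.int(q, n, replace = TRUE)
            ## per-community strength sums for O(deg) move evaluation
            Ksum <- vapply(seq_len(q), function(c) sum(k[lab == c]),
                           numeric(1))
            H <- .rb_hamiltonian(A, k, two_m, gamma_rb, lab)
            temp <- t0
            acc <- 0L; tries <- 0L
            for (sw in seq_len(sweeps)) {
                for (step in seq_len(n)) {
                    v <- sample.int(n, 1)
                    s_old <- lab[v]
                    s_new <- sample.int(q, 1)
                    if (s_new == s_old) next
                    tries <- tries + 1L
                    a_row <- A[v, ]
                    link_old <- sum(a_row[lab == s_old]) - a_row[v] *
                        (lab[v] == s_old)
                    link_new <- sum(a_row[lab == s_new])
                    q_old <- link_old -
                        gamma_rb * k[v] * (Ksum[s_old] - k[v]) / two_m
                    q_new <- link_new -
                        gamma_rb * k[v] * Ksum[s_new] / two_m
                    dH <- q_old - q_new
                    if (dH < 0 || runif(1) < exp(-dH / temp)) {
                        lab[v] <- s_new
                        Ksum[s_old] <- Ksum[s_old] - k[v]
                        Ksum[s_new] <- Ksum[s_new] + k[v]
                        H <- H + dH
                        acc <- acc + 1L
                    }
                }
                temp <- temp * cooling
            }
            trace$restarts <- rbind(trace$restarts,
                data.frame(component = ci, restart = r, final_H = H,
                           acceptance = acc / max(1L, tries)))
            if (H < best_H) { best_H <- H; best_lab <- lab }
        }
        membership[igraph::V(sub)$name] <- offset +
            match(best_lab, unique(best_lab))
        offset <- max(membership)
    }
    ## relabel by module size, largest first
    sizes <- sort(table(membership), decreasing = TRUE)
    remap <- setNames(seq_along(sizes), names(sizes))
    membership <- setNames(as.integer(remap[as.character(membership)]),
                           names(membership))
    has_w <- !is.null(igraph::E(network)$weight)
    A_all <- igraph::as_adjacency_matrix(network, sparse = FALSE,
        attr = if (has_w) "weight" else NULL)
    k_all <- rowSums(A_all)
    H_all <- .rb_hamiltonian(A_all, k_all, sum(k_all), gamma_rb,
                             membership[rownames(A_all)])
    structure(list(membership = membership,
                   labels = sprintf("PM%d", seq_along(sizes)),
                   hamiltonian = H_all, gamma_rb = gamma_rb,
                   trace = trace),
              class = "ModulePartition")
}

#' @export
print.ModulePartition <- function(x, ...) {
    cat(sprintf("ModulePartition: %d modules over %d nodes (H = %.4g)\n",
                length(x$labels), length(x$membership), x$hamiltonian))
    print(table(x$membership))
    invisible(x)
}

#' Per-module pathway and therapeutic-target enrichment
#'
#' For every module, enriches its genes against (i) the pathway gene sets,
#' (ii) the approved drug targets and (iii) the non-approved phased drug
#' targets (genes targeted only by drugs below the approval phase), each by
#' one-sided Fisher's exact test with BH FDR within module and category.
#'
#' @param partition a \code{ModulePartition}.
#' @param gene_sets named list of pathway sets.
#' @param drug_table data.frame from \code{\link{readDrugTable}}.
#' @param universe background gene universe.
#' @return data.frame in forest-plot layout: \code{module},
#'   \code{category}, plus the \code{\link{setEnrichment}} columns.
#' @export
moduleEnrichment <- function(partition, gene_sets, drug_table, universe) {
    approved <- unique(drug_table$target[drug_table$approved])
    phased <- setdiff(unique(drug_table$target[!drug_table$approved]),
                      approved)
    mods <- split(names(partition$membership), partition$membership)
    names(mods) <- partition$labels[as.integer(names(mods))]
    rows <- lapply(names(mods), function(m) {
        q <- intersect(mods[[m]], universe)
        if (length(q) == 0) return(NULL)
        pw <- setEnrichment(q, gene_sets, universe)
        pw$category <- "pathway"
        dr <- setEnrichment(q,
            list(approved_drug_targets = approved,
                 phased_drug_targets = phased), universe)
        ## the two therapeutic categories are separate families
        dr$fdr <- dr$p
        dr$category <- c("approved", "phased")
        out <- rbind(pw, dr)
        out$module <- m
        out
    })
    out <- do.call(rbind, rows)
    out[, c("module", "category", setdiff(names(out),
                                          c("module", "category")))]
}
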