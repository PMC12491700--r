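## Benchmarking: recovery-area metric over clinical proof-of-concept
## targets, leave-one-out predictor robustness, the RWR seeding harness for
## external gene lists, and the gamma x method sweep.

#' Area under the target-recovery curve
#'
#' Builds the step curve of cumulative benchmark-target recall against
#' normalised rank, truncated at \code{top_fraction} of the list, and
#' integrates it (normalised by the truncation so a perfect ranking scores
#' close to 1 and a random one close to 0.5).  With \code{top_fraction = 1}
#' this is the rank-AUC of targets against non-targets up to the
#' finite-sample plateau term.
#'
#' @param table a \linkS4class{PriorityTable} (or a character vector of gene
#'   ids already in rank order).
#' @param targets character vector of benchmark target genes.
#' @param top_fraction evaluation prefix in (0, 1].
#' @param label label carried on the result.
#' @return list (class \code{BenchmarkResult}): \code{label}, \code{area},
#'   \code{n_recovered} at the truncation, \code{target_ranks}.
#' @export
recoveryArea <- function(table, targets, top_fraction = 1,
                         label = "benchmark") {
    ranked <- if (is(table, "PriorityTable")) rankedGenes(table)
              else as.character(table)
    if (top_fraction <= 0 || top_fraction > 1)
        stop("top_fraction must be in (0, 1]")
    n <- length(ranked)
    hits <- ranked %in% targets
    m <- sum(hits)
    if (m == 0) stop("no target in ranking")
    L <- max(1L, floor(top_fraction * n + 1e-9))
    recall <- cumsum(hits) / m
    area <- sum(recall[seq_len(L)]) / n / top_fraction
    ranks <- which(hits)
    structure(list(label = label, area = area,
                   n_recovered = sum(hits[seq_len(L)]),
                   target_ranks = setNames(ranks, ranked[ranks])),
              class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
    cat(sprintf("BenchmarkResult '%s': area = %.4f, %d target(s) recovered\n",
                x$label, x$area, x$n_recovered))
    invisible(x)
}

#' Leave-one-out predictor robustness
#'
#' Runs the full prioritise-and-evaluate pipeline once with all predictors
#' and once per excluded predictor group, quantifying how much each group of
#' evidence contributes to target recovery.
#'
#' @param pm a \linkS4class{PredictorMatrix}.
#' @param groups named list mapping group label to predictor column names;
#'   defaults to one group per column.
#' @param targets benchmark target genes.
#' @param method combination method.
#' @param top_fraction evaluation prefix.
#' @return list of \code{BenchmarkResult}, labelled \code{"all"} and
#'   \code{"minus:<group>"}.
#' @export
leaveOneOut <- function(pm, groups = NULL, targets,
                        method = "order", top_fraction = 1) {
    af <- affinityMatrix(pm)
    if (is.null(groups))
        groups <- setNames(as.list(colnames(af)), colnames(af))
    if (length(groups) < 2) stop("need at least 2 predictor groups")
    sub_pm <- function(cols) {
        new("PredictorMatrix", affinity = af[, cols, drop = FALSE],
            seeded = seededCells(pm)[, cols, drop = FALSE],
            gamma = pm@gamma)
    }
    run <- function(cols, label) {
        pt <- prioritise(sub_pm(cols), method = method)
        recoveryArea(pt, targets, top_fraction = top_fraction, label = label)
    }
    out <- list(run(colnames(af), "all"))
    for (grp in names(groups)) {
        cols <- setdiff(colnames(af), groups[[grp]])
        if (length(cols) == 0)
            stop("excluding group '", grp, "' leaves zero predictors")
        out <- c(out, list(run(cols, paste0("minus:", grp))))
    }
    names(out) <- vapply(out, `[[`, character(1), "label")
    out
}

#' Rank genes by network affinity from an external seed list
#'
#' The harness used to give external gene lists network evidence: seeds are
#' propagated by restart walk and all network genes are ranked by their
#' steady-state affinity (ties rank lexicographically).
#'
#' @param seeds named numeric seed scores.
#' @param network undirected weighted igraph.
#' @param gamma restart probability (\code{gamma = 1} ranks by seed score
#'   alone).
#' @param method adjacency normalisation.
#' @return data.frame \code{gene}, \code{affinity}, \code{rank}.
#' @export
seedAndRank <- function(seeds, network, gamma = 0.3, method = "symmetric") {
    aff <- rwr(network, seeds, gamma = gamma, method = method)
    ord <- order(-aff, names(aff))
    data.frame(gene = names(aff)[ord], affinity = unname(aff)[ord],
               rank = seq_along(aff), stringsAsFactors = FALSE)
}

#' Sweep combination methods against restart probabilities
#'
#' The heatmap-style tuning grid: for every (method, gamma) pair the
#' predictor matrix is rebuilt, genes prioritised and the recovery area
#' computed.
#'
#' @param network igraph.
#' @param seed_lists per-predictor seed scores (see
#'   \code{\link{buildPredictorMatrix}}).
#' @param targets benchmark targets.
#' @param methods combination methods to try.
#' @param gammas restart probabilities to try.
#' @param top_fraction evaluation prefix.
#' @return data.frame \code{method}, \code{gamma}, \code{area}.
#' @export
sweepGrid <- function(network, seed_lists, targets,
                      methods = c("fisher", "logistic", "order"),
                      gammas = seq(0.1, 0.9, by = 0.1),
                      top_fraction = 1) {
    grid <- expand.grid(method = methods, gamma = gammas,
                        stringsAsFactors = FALSE)
    grid$area <- vapply(seq_len(nrow(grid)), function(i) {
        pm <- buildPredictorMatrix(network, seed_lists,
                                   gamma = grid$gamma[i])
        pt <- prioritise(pm, method = grid$method[i])
        recoveryArea(pt, targets, top_fraction = top_fraction)$area
    }, numeric(1))
    grid
}
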