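## Meta-analytic target prioritisation: affinity -> P-like values per
## predictor, combination across predictors (Fisher / logit / order
## statistic), then min-max rescaling of -log combined P to 0-10 ratings.

#' Convert affinities to P-like values per predictor
#'
#' Within each predictor column the P-like value of a gene is the
#' complementary empirical CDF share \eqn{P = \#\{AF' \ge AF\}/K} over all K
#' genes, so the top-affinity gene gets \eqn{1/K} and the bottom gets 1.
#' Cells with zero affinity (gene unreachable from that predictor's seeds)
#' are non-informative and returned as \code{NA}; the per-gene count of
#' informative predictors is \code{J}.
#'
#' @param pm a \linkS4class{PredictorMatrix}.
#' @return list with \code{P} (genes x predictors matrix, \code{NA} where
#'   non-informative) and \code{J} (named integer vector).
#' @export
affinityToP <- function(pm) {
    af <- affinityMatrix(pm)
    if (nrow(af) == 0) stop("empty predictor matrix")
    K <- nrow(af)
    P <- af
    for (j in seq_len(ncol(af))) {
        col <- af[, j]
        if (length(unique(col)) == 1) {
            warning("constant affinity column '", colnames(af)[j],
                    "': all P set to 1")
            P[, j] <- 1
        } else {
            ## complementary eCDF: number of genes at least as good, over K
            r <- rank(-col, ties.method = "max")
            P[, j] <- r / K
        }
    }
    P[af == 0] <- NA_real_
    J <- rowSums(!is.na(P))
    list(P = P, J = setNames(as.integer(J), rownames(af)))
}

#' Fisher's combination of P-values
#'
#' \eqn{x = -2\sum \ln P} referred to the upper tail of a chi-squared
#' distribution with 2J degrees of freedom.
#'
#' @param p_row numeric vector of P-values in (0, 1].
#' @return list \code{x}, \code{cp} (combined P) and \code{log_cp} (natural
#'   log of the combined P, exact at extreme significance).
#' @export
combineFisher <- function(p_row) {
    p_row <- p_row[!is.na(p_row)]
    if (length(p_row) == 0) stop("empty P-value row")
    if (any(p_row <= 0 | p_row > 1)) stop("P-values must lie in (0, 1]")
    J <- length(p_row)
    x <- -2 * sum(log(p_row))
    log_cp <- pchisq(x, df = 2 * J, lower.tail = FALSE, log.p = TRUE)
    list(x = unname(x), cp = exp(unname(log_cp)), log_cp = unname(log_cp))
}

#' Logit (Mudholkar-George) combination of P-values
#'
#' \eqn{t = -\sum \ln(P/(1-P)) \sqrt{3(5J+4)/(J\pi^2(5J+2))}} referred to the
#' upper tail of Student's t with 5J + 4 degrees of freedom.
#'
#' @param p_row numeric vector of P-values strictly inside (0, 1); clip
#'   boundary values before calling.
#' @return list \code{x}, \code{cp}, \code{log_cp}.
#' @export
combineLogistic <- function(p_row) {
    p_row <- p_row[!is.na(p_row)]
    if (length(p_row) == 0) stop("empty P-value row")
    if (any(p_row <= 0 | p_row >= 1))
        stop("logit combination requires P strictly inside (0, 1)")
    J <- length(p_row)
    scale <- sqrt(3 * (5 * J + 4) / (J * pi^2 * (5 * J + 2)))
    x <- -sum(log(p_row / (1 - p_row))) * scale
    log_cp <- pt(x, df = 5 * J + 4, lower.tail = FALSE, log.p = TRUE)
    list(x = unname(x), cp = exp(unname(log_cp)), log_cp = unname(log_cp))
}

#' Order-statistic combination of P-values
#'
#' The default mode refers the largest order statistic
#' \eqn{x = P_{(J)}} to the lower tail of Beta(J, 1), giving the closed form
#' \eqn{CP = x^J}.  The generalised mode refers the k-th order statistic to
#' Beta(k, J - k + 1).
#'
#' @param p_row numeric vector of P-values in (0, 1].
#' @param order_k \code{"max"} (default) or an integer in 1..J.
#' @return list \code{x}, \code{cp}, \code{log_cp}.
#' @export
combineOrder <- function(p_row, order_k = "max") {
    p_row <- p_row[!is.na(p_row)]
    if (length(p_row) == 0) stop("empty P-value row")
    if (any(p_row <= 0 | p_row > 1)) stop("P-values must lie in (0, 1]")
    J <- length(p_row)
    ps <- sort(p_row)
    if (identical(order_k, "max")) {
        x <- ps[J]
        log_cp <- pbeta(x, J, 1, log.p = TRUE)
    } else {
        k <- as.integer(order_k)
        if (is.na(k) || k < 1 || k > J)
            stop("order_k out of range 1..J")
        x <- ps[k]
        log_cp <- pbeta(x, k, J - k + 1, log.p = TRUE)
    }
    list(x = unname(x), cp = exp(unname(log_cp)), log_cp = unname(log_cp))
}

#' Rescale combined P-values to 0-10 priority ratings
#'
#' \eqn{PR_i = 10 (\,-\log CP_i - \min_k\,)/(\max_k - \min_k)}: the most
#' significant gene gets 10, the least 0 (the rating is invariant to the
#' logarithm base).  Ranks order by rating descending, ties broken
#' lexicographically by gene id.
#'
#' @param genes character vector of gene ids.
#' @param log_cp natural-log combined P-values (one per gene).
#' @param statistic,J,method companion columns for the table.
#' @return a \linkS4class{PriorityTable}.
#' @export
ratePriorities <- function(genes, log_cp, statistic = NA_real_,
                           J = NA_integer_, method = "unspecified") {
    if (length(genes) < 2) stop("need at least 2 genes to rate")
    if (anyDuplicated(genes)) stop("duplicate gene ids")
    ml <- -log_cp / log(10)   # -log10 CP, any base gives identical ratings
    if (max(ml) - min(ml) < .Machine$double.eps * max(1, abs(max(ml))))
        stop("degenerate rating range: all combined P equal")
    rating <- 10 * (ml - min(ml)) / (max(ml) - min(ml))
    ord <- order(-rating, genes)
    rank <- integer(length(genes))
    rank[ord] <- seq_along(genes)
    tb <- data.frame(gene = genes, method = method,
                     J = rep_len(J, length(genes)),
                     statistic = rep_len(statistic, length(genes)),
                     combined_p = exp(log_cp), log10_cp = log_cp / log(10),
                     rating = rating, rank = rank, stringsAsFactors = FALSE)
    new("PriorityTable", table = tb, method = method)
}

#' Prioritise genes from a predictor matrix
#'
#' Full combination stage: converts affinities to P-like values, combines
#' each gene's informative predictors by the chosen method and rescales to
#' ratings.  Genes informative under no predictor are dropped.  For the
#' logit method, boundary values P = 1 are clipped to \code{1 - 1e-6}
#' (the logit is undefined at 1).
#'
#' @param pm a \linkS4class{PredictorMatrix}.
#' @param method \code{"order"} (default), \code{"fisher"} or
#'   \code{"logistic"}.
#' @param order_k passed to \code{\link{combineOrder}}.
#' @return a \linkS4class{PriorityTable}.
#' @examples
#' g <- igraph::make_ring(5)
#' igraph::V(g)$name <- letters[1:5]
#' igraph::E(g)$weight <- 1
#' pm <- buildPredictorMatrix(g, list(p1 = c(a = 1), p2 = c(c = 1)), 0.5)
#' priorityTable(prioritise(pm, "fisher"))
#' @export
prioritise <- function(pm, method = c("order", "fisher", "logistic"),
                       order_k = "max") {
    method <- match.arg(method)
    conv <- affinityToP(pm)
    keep <- conv$J >= 1
    P <- conv$P[keep, , drop = FALSE]
    if (nrow(P) < 2) stop("fewer than 2 genes with informative predictors")
    combine <- switch(method,
        fisher = combineFisher,
        logistic = function(p) combineLogistic(pmin(p, 1 - 1e-6)),
        order = function(p) combineOrder(p, order_k = order_k))
    res <- apply(P, 1, function(p) {
        r <- combine(p[!is.na(p)])
        c(x = r$x, log_cp = r$log_cp, J = sum(!is.na(p)))
    })
    ratePriorities(rownames(P), log_cp = res["log_cp", ],
                   statistic = res["x", ], J = as.integer(res["J", ]),
                   method = method)
}
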