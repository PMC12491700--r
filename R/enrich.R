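## Gene-set over-representation statistics shared by the map clustering,
## crosstalk and intervention stages: one-sided hypergeometric P, Z-score
## from the hypergeometric mean/variance, sample odds ratio with Haldane
## correction and Woolf logit confidence interval, BH false discovery rate.

#' One-sided gene-set enrichment of a query gene set
#'
#' For each set the 2x2 table of query membership against set membership
#' over the universe is summarised by the hypergeometric upper-tail P-value,
#' the Z-score \eqn{(k - \mu)/\sigma} with the hypergeometric mean and
#' variance, the sample odds ratio (Haldane 0.5 correction when any cell is
#' zero) with its Woolf logit 95\% confidence interval, and the
#' Benjamini-Hochberg FDR across the supplied sets.
#'
#' @param query character vector of query genes (must lie in the universe).
#' @param sets named list of character vectors.
#' @param universe character vector of background genes.
#' @return data.frame: \code{set}, \code{overlap} k, \code{set_size} K,
#'   \code{query_size} n, \code{universe_size} N, \code{z}, \code{odds_ratio},
#'   \code{ci_lo}, \code{ci_hi}, \code{p}, \code{fdr}.
#' @examples
#' setEnrichment(paste0("g", 1:10),
#'               list(s = paste0("g", 1:10)), paste0("g", 1:100))
#' @export
setEnrichment <- function(query, sets, universe) {
    universe <- unique(universe)
    if (length(universe) == 0) stop("empty universe")
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query genes must be a subset of the universe")
    n <- length(query)
    N <- length(universe)
    rows <- lapply(names(sets), function(nm) {
        set_u <- intersect(unique(sets[[nm]]), universe)
        K <- length(set_u)
        k <- length(intersect(query, set_u))
        p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        mu <- n * K / N
        sig2 <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
        z <- if (sig2 > 0) (k - mu) / sqrt(sig2) else NA_real_
        a <- k; b <- n - k; cc <- K - k; d <- N - n - K + k
        if (min(a, b, cc, d) == 0) {
            a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
        }
        or <- (a * d) / (b * cc)
        se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
        data.frame(set = nm, overlap = k, set_size = K, query_size = n,
                   universe_size = N, z = z, odds_ratio = or,
                   ci_lo = exp(log(or) - qnorm(0.975) * se),
                   ci_hi = exp(log(or) + qnorm(0.975) * se),
                   p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}
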