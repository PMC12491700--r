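## Core-gene scoring: per-SNP GWAS scores, then gene scores from genomic
## proximity and from QTL / chromatin-conformation link evidence under the
## maximum scoring scheme.

#' Score SNPs from GWAS P-values, the significance threshold and LD strength
#'
#' The SNP score is
#' \deqn{S = R^2 [\log_{10}((1-P)/P) - \log_{10}((1-T)/T)]}
#' with \eqn{T} the lead-SNP significance threshold (default 5e-8), so a SNP
#' exactly at the threshold (or with \eqn{R^2 = 0}) scores 0.  LD proxies
#' with P above the threshold would score negative and are clamped to 0:
#' scores seed a random walk and must be non-negative.
#'
#' @param snps data.frame from \code{\link{readGwas}} (columns \code{snp_id},
#'   \code{p_value}, \code{r2}, ...).
#' @param lead_p_threshold genome-wide significance threshold T.
#' @return the input with an added non-negative \code{s_snp} column.
#' @export
scoreSnps <- function(snps, lead_p_threshold = 5e-8) {
    stopifnot(all(c("snp_id", "p_value", "r2") %in% names(snps)))
    p <- snps$p_value
    if (any(p <= 0)) stop("degenerate p-value: P must be > 0")
    if (any(p > 1)) stop("p-values must be <= 1")
    t0 <- lead_p_threshold
    raw <- snps$r2 * (log10((1 - p) / p) - log10((1 - t0) / t0))
    snps$s_snp <- pmax(0, raw)
    snps
}

#' Score genes by genomic proximity to scored SNPs
#'
#' A gene's proximity score is the maximum SNP score over all SNPs whose
#' position falls within \code{window_bp} of the gene body (1-based closed
#' interval \code{[start - window, end + window]}, same chromosome).  Genes
#' with no SNP in the window are omitted.
#'
#' @param scored_snps output of \code{\link{scoreSnps}} with \code{chrom},
#'   \code{pos} columns.
#' @param annotations gene intervals from \code{\link{readAnnotations}}.
#' @param window_bp window size in bp (default 20 kb).
#' @return data.frame \code{gene_id}, \code{predictor = "proximity"},
#'   \code{score}, \code{snps} (comma-joined contributing SNP ids).
#' @export
scoreProximity <- function(scored_snps, annotations, window_bp = 20000L) {
    stopifnot("s_snp" %in% names(scored_snps))
    rows <- lapply(seq_len(nrow(annotations)), function(i) {
        a <- annotations[i, ]
        hit <- scored_snps$chrom == a$chrom &
               scored_snps$pos >= a$start - window_bp &
               scored_snps$pos <= a$end + window_bp
        if (!any(hit)) return(NULL)
        data.frame(gene_id = a$gene_id, predictor = "proximity",
                   score = max(scored_snps$s_snp[hit]),
                   snps = paste(unique(scored_snps$snp_id[hit]),
                                collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene_id = character(0), predictor = character(0),
                          score = numeric(0), snps = character(0))
    rownames(out) <- NULL
    out
}

#' Score genes from SNP-gene link evidence (QTL or conformation)
#'
#' Each link's strength is transformed to \eqn{x = -\log_{10}(strength)} and
#' weighted by the empirical CDF of x over all links in the evidence table
#' (right-continuous, \code{eCDF(x) = \#\{x' <= x\}/n}, so the strongest link
#' gets weight 1).  A (SNP, gene) link contributes
#' \eqn{S_{SNP} \times eCDF(x)}; the gene score is the maximum contribution
#' over its linked SNPs.  The eCDF is estimated per evidence table, keeping
#' each predictor self-contained.
#'
#' @param scored_snps output of \code{\link{scoreSnps}}.
#' @param evidence data.frame from \code{\link{readEvidence}}.
#' @param evidence_kind \code{"qtl"} or \code{"conformation"}; names the
#'   predictor.
#' @return data.frame \code{gene_id}, \code{predictor}, \code{score},
#'   \code{snps}.  Rows referencing SNPs absent from \code{scored_snps} are
#'   dropped with a message.
#' @export
scoreEvidence <- function(scored_snps, evidence,
                          evidence_kind = c("qtl", "conformation")) {
    evidence_kind <- match.arg(evidence_kind)
    stopifnot("s_snp" %in% names(scored_snps),
              all(c("snp_id", "gene_id", "strength") %in% names(evidence)))
    known <- evidence$snp_id %in% scored_snps$snp_id
    if (any(!known))
        message(sum(!known), " evidence row(s) referencing unknown SNPs ",
                "dropped")
    ev <- evidence[known, , drop = FALSE]
    if (nrow(ev) == 0)
        return(data.frame(gene_id = character(0), predictor = character(0),
                          score = numeric(0), snps = character(0)))
    x <- -log10(ev$strength)
    F <- ecdf(x)
    s_map <- setNames(scored_snps$s_snp, scored_snps$snp_id)
    ev$contribution <- s_map[ev$snp_id] * F(x)
    best <- vapply(split(ev, ev$gene_id), function(d) {
        j <- which.max(d$contribution)
        c(score = d$contribution[j])
    }, numeric(1))
    snps <- vapply(split(ev, ev$gene_id), function(d)
        paste(unique(d$snp_id), collapse = ","), character(1))
    out <- data.frame(gene_id = names(best), predictor = evidence_kind,
                      score = unname(best), snps = unname(snps),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
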