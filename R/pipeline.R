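#' Score all core-gene predictors from raw inputs
#'
#' Convenience wrapper for the core-gene scoring stage: scores SNPs, then
#' derives the proximity, QTL and conformation seed-gene scores.
#'
#' @param gwas data.frame from \code{\link{readGwas}}.
#' @param annotations data.frame from \code{\link{readAnnotations}}.
#' @param evidence_qtl,evidence_pchic link tables from
#'   \code{\link{readEvidence}} (either may be \code{NULL}).
#' @param config a \code{\link{runConfig}}.
#' @return named list of seed-score data.frames (one per predictor), ready
#'   for \code{\link{buildPredictorMatrix}}.
#' @export
buildSeedScores <- function(gwas, annotations, evidence_qtl = NULL,
                            evidence_pchic = NULL, config = runConfig()) {
    gwas <- gwas[gwas$r2 >= config$ld_r2_threshold, , drop = FALSE]
    scored <- scoreSnps(gwas, config$lead_p_threshold)
    out <- list(proximity = scoreProximity(scored, annotations,
                                           config$window_bp))
    if (!is.null(evidence_qtl))
        out$qtl <- scoreEvidence(scored, evidence_qtl, "qtl")
    if (!is.null(evidence_pchic))
        out$conformation <- scoreEvidence(scored, evidence_pchic,
                                          "conformation")
    out[vapply(out, nrow, integer(1)) > 0]
}

#' Run the full prioritisation pipeline on a cohort
#'
#' Scores SNPs and core genes, propagates each predictor's seeds over the
#' network by restart walk, and combines the per-predictor affinities into
#' a priority table.
#'
#' @param cohort list as returned by \code{\link{genCohort}} (or assembled
#'   from the readers).
#' @param config a \code{\link{runConfig}}.
#' @return list: \code{seed_scores}, \code{pm}
#'   (\linkS4class{PredictorMatrix}), \code{priority}
#'   (\linkS4class{PriorityTable}).
#' @export
prioritiseCohort <- function(cohort, config = runConfig()) {
    seeds <- buildSeedScores(cohort$gwas, cohort$annotations,
                             cohort$evidence_qtl, cohort$evidence_pchic,
                             config)
    pm <- buildPredictorMatrix(cohort$network, seeds,
                               gamma = config$restart_probability)
    pt <- prioritise(pm, method = config$combine_method)
    list(seed_scores = seeds, pm = pm, priority = pt)
}
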