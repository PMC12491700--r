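#' Run configuration
#'
#' Bundles the tunable parameters of the whole pipeline with the framework's
#' published defaults: restart probability 0.3, gene window 20 kb, lead-SNP
#' significance 5e-8, LD threshold R^2 >= 0.8, order-statistic combination,
#' 100 permutation iterations and a top-1\% evaluation prefix.
#'
#' @param restart_probability random-walk restart probability gamma in (0,1).
#' @param window_bp gene-proximity window in base pairs (>= 0).
#' @param lead_p_threshold genome-wide significance threshold in (0,1).
#' @param ld_r2_threshold minimum LD R^2 for proxy SNPs, in (0,1).
#' @param combine_method one of \code{"fisher"}, \code{"logistic"},
#'   \code{"order"}.
#' @param rng_seed integer seed controlling every stochastic stage.
#' @param permutation_iters permutation count for the crosstalk test (>= 1).
#' @param top_fraction evaluation prefix as a fraction of the ranking, (0,1].
#'
#' @return a named list of validated parameters with class \code{"RunConfig"}.
#' @examples
#' cfg <- runConfig()
#' cfg$restart_probability
#' @export
runConfig <- function(restart_probability = 0.3,
                      window_bp = 20000L,
                      lead_p_threshold = 5e-8,
                      ld_r2_threshold = 0.8,
                      combine_method = c("order", "fisher", "logistic"),
                      rng_seed = 1L,
                      permutation_iters = 100L,
                      top_fraction = 0.01) {
    combine_method <- match.arg(combine_method)
    stopifnot(
        "restart_probability must be in (0,1)" =
            is.numeric(restart_probability) && length(restart_probability) == 1 &&
            restart_probability > 0 && restart_probability < 1,
        "window_bp must be a non-negative integer" =
            is.numeric(window_bp) && window_bp >= 0,
        "lead_p_threshold must be in (0,1)" =
            lead_p_threshold > 0 && lead_p_threshold < 1,
        "ld_r2_threshold must be in (0,1)" =
            ld_r2_threshold > 0 && ld_r2_threshold < 1,
        "rng_seed must be a single integer" =
            is.numeric(rng_seed) && length(rng_seed) == 1,
        "permutation_iters must be >= 1" = permutation_iters >= 1,
        "top_fraction must be in (0,1]" =
            top_fraction > 0 && top_fraction <= 1)
    cfg <- list(restart_probability = as.numeric(restart_probability),
                window_bp = as.integer(window_bp),
                lead_p_threshold = as.numeric(lead_p_threshold),
                ld_r2_threshold = as.numeric(ld_r2_threshold),
                combine_method = combine_method,
                rng_seed = as.integer(rng_seed),
                permutation_iters = as.integer(permutation_iters),
                top_fraction = as.numeric(top_fraction))
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' \code{\link{runConfig}}.
#'
#' @param path YAML file.
#' @return a \code{RunConfig} list.
#' @export
readConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    known <- names(formals(runConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad) > 0)
        stop("unknown config keys: ", paste(bad, collapse = ", "))
    do.call(runConfig, vals)
}
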