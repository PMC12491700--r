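#' @import methods
#' @importFrom stats aggregate approx cor dist ecdf kmeans median na.omit
#'   p.adjust pbeta pchisq phyper pnorm prcomp pt qnorm quantile runif
#'   rnorm sd setNames
#' @importFrom utils combn head read.delim write.table
NULL

#' Gene-by-predictor affinity matrix
#'
#' Central intermediate of the prioritisation framework: one column per
#' predictor (e.g. proximity, QTL, conformation), one row per network gene,
#' holding the random-walk-with-restart steady-state affinity of that gene to
#' the predictor's seed set.  Each column sums to one (the walk conserves
#' probability mass) and carries per-cell provenance distinguishing seed genes
#' from genes reached only by propagation.
#'
#' @slot affinity numeric matrix, genes x predictors, values in [0, 1].
#' @slot seeded logical matrix of the same shape; \code{TRUE} where the gene
#'   was a seed of that predictor.
#' @slot gamma restart probability used for the propagation.
#'
#' @exportClass PredictorMatrix
setClass("PredictorMatrix",
    representation(affinity = "matrix", seeded = "matrix", gamma = "numeric"))

setValidity("PredictorMatrix", function(object) {
    af <- object@affinity
    if (!is.numeric(af) || is.null(rownames(af)) || is.null(colnames(af)))
        return("affinity must be a numeric matrix with row and column names")
    if (any(!is.finite(af)) || any(af < -1e-12) || any(af > 1 + 1e-12))
        return("affinities must be finite and within [0, 1]")
    if (!identical(dim(af), dim(object@seeded)))
        return("seeded provenance must match affinity dimensions")
    if (length(object@gamma) != 1 || object@gamma <= 0 || object@gamma > 1)
        return("gamma must be a single value in (0, 1]")
    TRUE
})

#' Per-gene combined evidence and priority ratings
#'
#' Result of meta-analytic combination of per-predictor P-like values:
#' for every gene the combination statistic, the combined P-value under the
#' method's reference distribution (chi-squared 2J for Fisher, Student t
#' 5J+4 for logit, Beta(J, 1) for the order statistic), the 0-10 priority
#' rating and the rank (1 = top priority).
#'
#' @slot table data.frame with columns \code{gene}, \code{method}, \code{J},
#'   \code{statistic}, \code{combined_p}, \code{log10_cp}, \code{rating},
#'   \code{rank}.
#' @slot method combination method tag.
#'
#' @exportClass PriorityTable
setClass("PriorityTable",
    representation(table = "data.frame", method = "character"))

setValidity("PriorityTable", function(object) {
    tb <- object@table
    need <- c("gene", "method", "J", "statistic", "combined_p", "log10_cp",
              "rating", "rank")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (nrow(tb) > 0) {
        if (any(tb$rating < -1e-9) || any(tb$rating > 10 + 1e-9))
            return("ratings must lie in [0, 10]")
        if (!identical(sort(tb$rank), seq_len(nrow(tb))))
            return("ranks must be a permutation of 1..K")
        if (anyDuplicated(tb$gene))
            return("gene ids must be unique")
    }
    TRUE
})

#' Supra-hexagonal self-organising map
#'
#' A lattice of concentric hexagon rings (r rings give 3r^2 - 3r + 1 nodes),
#' each node carrying a 2-D location vector on the grid and an M-dimensional
#' codebook vector learned by sequential SOM training.
#'
#' @slot rings number of rings r (r = 1 is the single centre node).
#' @slot coords N x 2 matrix of node location vectors (Euclidean plane).
#' @slot ring integer ring index of each node (1 = centre).
#' @slot neighbours list of integer vectors: hex-grid 6-neighbourhood
#'   (fewer on the rim).
#' @slot codebook N x M matrix of codebook vectors (NA until trained).
#' @slot trained logical; \code{TRUE} after training.
#' @slot qe numeric(2): mean quantization error before and after training.
#'
#' @exportClass SupraHexMap
setClass("SupraHexMap",
    representation(rings = "integer", coords = "matrix", ring = "integer",
                   neighbours = "list", codebook = "matrix",
                   trained = "logical", qe = "numeric"))

setValidity("SupraHexMap", function(object) {
    r <- object@rings
    n_expect <- 3L * r^2 - 3L * r + 1L
    if (nrow(object@coords) != n_expect)
        return(sprintf("a %d-ring map must have %d nodes", r, n_expect))
    if (length(object@neighbours) != n_expect)
        return("neighbour list must cover every node")
    if (object@trained && any(!is.finite(object@codebook)))
        return("trained codebooks must be finite")
    TRUE
})

#' Prize-collecting Steiner subnetwork
#'
#' A connected acyclic subnetwork (tree) of the prize graph selected to
#' maximise total node prize minus scaled edge cost, with the permutation
#' P-value of its objective when the significance test has been run.
#'
#' @slot nodes character vector of selected gene ids.
#' @slot edges data.frame of tree edges (\code{from}, \code{to}, \code{cost}).
#' @slot prizes named numeric prizes of the selected nodes.
#' @slot objective numeric: sum(prizes) - lambda * sum(costs).
#' @slot lambda edge-cost scale at which the tree was extracted.
#' @slot pvalue permutation P-value (NA before testing).
#' @slot target_n requested node count (NA if unconstrained).
#'
#' @exportClass CrosstalkResult
setClass("CrosstalkResult",
    representation(nodes = "character", edges = "data.frame",
                   prizes = "numeric", objective = "numeric",
                   lambda = "numeric", pvalue = "numeric",
                   target_n = "numeric"))

setValidity("CrosstalkResult", function(object) {
    nn <- length(object@nodes)
    if (nn > 0 && nrow(object@edges) != nn - 1L)
        return("a crosstalk on n nodes must be a tree with n - 1 edges")
    if (length(object@prizes) != nn)
        return("prizes must cover exactly the selected nodes")
    obj <- sum(object@prizes) - object@lambda * sum(object@edges$cost)
    if (nn > 0 && abs(obj - object@objective) > 1e-8 * max(1, abs(obj)))
        return("objective does not match recomputation from parts")
    TRUE
})
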