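#' @describeIn PredictorMatrix-accessors the genes x predictors affinity matrix
#' @export
setGeneric("affinityMatrix", function(x) standardGeneric("affinityMatrix"))

#' @describeIn PredictorMatrix-accessors logical matrix flagging seed cells
#' @export
setGeneric("seededCells", function(x) standardGeneric("seededCells"))

#' @describeIn PriorityTable-accessors the full per-gene table
#' @export
setGeneric("priorityTable", function(x) standardGeneric("priorityTable"))

#' @describeIn PriorityTable-accessors named 0-10 ratings
#' @export
setGeneric("ratings", function(x) standardGeneric("ratings"))

#' @describeIn PriorityTable-accessors gene ids in rank order (best first)
#' @export
setGeneric("rankedGenes", function(x) standardGeneric("rankedGenes"))

#' @describeIn SupraHexMap-accessors N x M codebook matrix
#' @export
setGeneric("codebook", function(x) standardGeneric("codebook"))

#' @describeIn SupraHexMap-accessors N x 2 node location vectors
#' @export
setGeneric("mapCoords", function(x) standardGeneric("mapCoords"))

#' @describeIn CrosstalkResult-accessors selected gene ids
#' @export
setGeneric("crosstalkGenes", function(x) standardGeneric("crosstalkGenes"))

#' @describeIn CrosstalkResult-accessors tree edge table
#' @export
setGeneric("crosstalkEdges", function(x) standardGeneric("crosstalkEdges"))

#' Accessors for PredictorMatrix
#' @param x a \linkS4class{PredictorMatrix}
#' @name PredictorMatrix-accessors
NULL

#' Accessors for PriorityTable
#' @param x a \linkS4class{PriorityTable}
#' @name PriorityTable-accessors
NULL

#' Accessors for SupraHexMap
#' @param x a \linkS4class{SupraHexMap}
#' @name SupraHexMap-accessors
NULL

#' Accessors for CrosstalkResult
#' @param x a \linkS4class{CrosstalkResult}
#' @name CrosstalkResult-accessors
NULL

#' @rdname PredictorMatrix-accessors
#' @export
setMethod("affinityMatrix", "PredictorMatrix", function(x) x@affinity)

#' @rdname PredictorMatrix-accessors
#' @export
setMethod("seededCells", "PredictorMatrix", function(x) x@seeded)

#' @rdname PriorityTable-accessors
#' @export
setMethod("priorityTable", "PriorityTable", function(x) x@table)

#' @rdname PriorityTable-accessors
#' @export
setMethod("ratings", "PriorityTable",
    function(x) setNames(x@table$rating, x@table$gene))

#' @rdname PriorityTable-accessors
#' @export
setMethod("rankedGenes", "PriorityTable",
    function(x) x@table$gene[order(x@table$rank)])

#' @rdname SupraHexMap-accessors
#' @export
setMethod("codebook", "SupraHexMap", function(x) x@codebook)

#' @rdname SupraHexMap-accessors
#' @export
setMethod("mapCoords", "SupraHexMap", function(x) x@coords)

#' @rdname CrosstalkResult-accessors
#' @export
setMethod("crosstalkGenes", "CrosstalkResult", function(x) x@nodes)

#' @rdname CrosstalkResult-accessors
#' @export
setMethod("crosstalkEdges", "CrosstalkResult", function(x) x@edges)

setMethod("show", "PredictorMatrix", function(object) {
    af <- object@affinity
    cat(sprintf("PredictorMatrix: %d genes x %d predictors (gamma = %g)\n",
        nrow(af), ncol(af), object@gamma))
    cat("  predictors:", paste(colnames(af), collapse = ", "), "\n")
    cat(sprintf("  seeds per predictor: %s\n",
        paste(colSums(object@seeded), collapse = ", ")))
})

setMethod("show", "PriorityTable", function(object) {
    tb <- object@table
    cat(sprintf("PriorityTable: %d genes, method '%s'\n",
        nrow(tb), object@method))
    top <- head(tb[order(tb$rank), c("gene", "combined_p", "rating", "rank")], 5)
    print(top, row.names = FALSE)
})

setMethod("show", "SupraHexMap", function(object) {
    cat(sprintf("SupraHexMap: %d rings, %d nodes, %s\n", object@rings,
        nrow(object@coords),
        if (object@trained) sprintf("trained (QE %.4g -> %.4g)",
            object@qe[1], object@qe[2]) else "untrained"))
})

setMethod("show", "CrosstalkResult", function(object) {
    cat(sprintf("CrosstalkResult: %d genes, objective %.4g (lambda = %.4g)\n",
        length(object@nodes), object@objective, object@lambda))
    if (!is.na(object@pvalue))
        cat(sprintf("  permutation P = %.4g\n", object@pvalue))
})
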