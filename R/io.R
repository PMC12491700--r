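## Readers and writers for every external table the framework touches.
## All inter-stage artifacts are plain TSV with a JSON provenance sidecar;
## coordinates are 1-based closed intervals (GWAS-catalog convention).

.read_tsv <- function(path, required) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                     stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(required, names(df))
    if (length(miss) > 0)
        stop("missing required column(s) in ", basename(path), ": ",
             paste(miss, collapse = ", "))
    df
}

.check_numeric <- function(df, col, path) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]))
    if (length(bad) > 0)
        stop("malformed row at line ", bad[1] + 1L, " of ", basename(path),
             ": non-numeric ", col)
    x
}

#' Read GWAS summary statistics
#'
#' Parses a tab-separated table of lead and LD-proxy SNPs with columns
#' \code{snp_id}, \code{chrom}, \code{pos}, \code{p_value}, \code{lead_id},
#' \code{r2}.  A lead SNP references itself with \code{r2 = 1}.  Records are
#' validated (P in (0,1], R^2 in [0,1], positive 1-based positions) and
#' deduplicated by (snp_id, lead_id).
#'
#' @param path TSV file.
#' @return data.frame of validated SNP records.
#' @export
readGwas <- function(path) {
    df <- .read_tsv(path, c("snp_id", "chrom", "pos", "p_value", "lead_id",
                            "r2"))
    df$pos <- .check_numeric(df, "pos", path)
    df$p_value <- .check_numeric(df, "p_value", path)
    df$r2 <- .check_numeric(df, "r2", path)
    if (any(is.na(df$snp_id)) || any(df$snp_id == ""))
        stop("malformed row at line ",
             which(is.na(df$snp_id) | df$snp_id == "")[1] + 1L,
             ": empty snp_id")
    if (any(df$p_value <= 0))
        stop("p_value out of range at line ", which(df$p_value <= 0)[1] + 1L,
             ": p-values must be > 0")
    if (any(df$p_value > 1))
        stop("p_value out of range at line ", which(df$p_value > 1)[1] + 1L)
    if (any(df$r2 < 0 | df$r2 > 1))
        stop("r2 out of range at line ",
             which(df$r2 < 0 | df$r2 > 1)[1] + 1L)
    if (any(df$pos < 1))
        stop("pos must be 1-based positive at line ",
             which(df$pos < 1)[1] + 1L)
    df <- df[!duplicated(df[, c("snp_id", "lead_id")]), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Read SNP-to-gene regulatory evidence
#'
#' Columns \code{snp_id}, \code{gene_id}, \code{strength}; the strength is
#' the significance (QTL association P) or interaction strength (PCHi-C)
#' of the SNP-gene link, in (0, 1].
#'
#' @param path TSV file.
#' @param kind \code{"qtl"} or \code{"conformation"}; recorded on the result.
#' @return data.frame with an \code{evidence_kind} column.
#' @export
readEvidence <- function(path, kind = c("qtl", "conformation")) {
    kind <- match.arg(kind)
    df <- .read_tsv(path, c("snp_id", "gene_id", "strength"))
    df$strength <- .check_numeric(df, "strength", path)
    if (any(df$strength <= 0 | df$strength > 1))
        stop("strength out of range (0,1] at line ",
             which(df$strength <= 0 | df$strength > 1)[1] + 1L)
    df$evidence_kind <- kind
    df
}

#' Read gene annotations
#'
#' BED-like TSV with 1-based closed intervals: \code{gene_id}, \code{chrom},
#' \code{start}, \code{end}.
#'
#' @param path TSV file.
#' @return data.frame of gene intervals.
#' @export
readAnnotations <- function(path) {
    df <- .read_tsv(path, c("gene_id", "chrom", "start", "end"))
    df$start <- .check_numeric(df, "start", path)
    df$end <- .check_numeric(df, "end", path)
    if (any(df$end < df$start))
        stop("end < start at line ", which(df$end < df$start)[1] + 1L)
    df
}

#' Read a weighted interaction network
#'
#' Edge-list TSV (\code{from}, \code{to}, \code{weight}) as an undirected
#' simple igraph; self-loops are rejected, duplicate edges collapsed to their
#' maximum weight.
#'
#' @param path TSV file.
#' @return an undirected weighted \code{igraph}.
#' @export
readNetwork <- function(path) {
    df <- .read_tsv(path, c("from", "to", "weight"))
    df$weight <- .check_numeric(df, "weight", path)
    if (any(df$weight <= 0))
        stop("edge weights must be > 0 at line ",
             which(df$weight <= 0)[1] + 1L)
    if (any(df$from == df$to))
        stop("self-loop at line ", which(df$from == df$to)[1] + 1L)
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
    igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}

#' Read a drug-target table
#'
#' Columns \code{drug}, \code{target}, \code{phase} (ordinal integer, the
#' maximum value meaning approval), \code{indication}.  Duplicate
#' (drug, target, indication) rows keep the highest phase.  An
#' \code{approved} flag marks rows at the table-wide maximum phase.
#'
#' @param path TSV file.
#' @return data.frame with an added logical \code{approved} column.
#' @export
readDrugTable <- function(path) {
    df <- .read_tsv(path, c("drug", "target", "phase", "indication"))
    df$phase <- .check_numeric(df, "phase", path)
    key <- paste(df$drug, df$target, df$indication, sep = "\r")
    df <- df[order(key, -df$phase), , drop = FALSE]
    df <- df[!duplicated(paste(df$drug, df$target, df$indication,
                               sep = "\r")), , drop = FALSE]
    df$approved <- df$phase >= max(df$phase)
    rownames(df) <- NULL
    df
}

#' Read a plain gene list (one id per line)
#' @param path text file.
#' @return character vector of unique gene ids.
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    x <- readLines(path, warn = FALSE)
    x <- trimws(x)
    unique(x[nzchar(x)])
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Set names must be unique; empty sets are an error; duplicate members
#' within a set are collapsed.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list()
    for (i in seq_along(lines)) {
        parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3)
            stop("empty set at line ", i, ": '", parts[1],
                 "' has no member genes")
        nm <- parts[1]
        if (nm %in% names(sets))
            stop("duplicate set name: ", nm)
        members <- unique(parts[-(1:2)])
        members <- members[nzchar(members)]
        if (length(members) == 0)
            stop("empty set at line ", i, ": '", nm, "' has no member genes")
        sets[[nm]] <- members
    }
    sets
}

#' Write gene sets to GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGmt <- function(sets, path) {
    stopifnot(length(names(sets)) == length(sets))
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write a table as TSV with a JSON provenance sidecar
#'
#' The sidecar (\code{<path>.json}) records the producing stage, the run
#' configuration, the seed and MD5 hashes of declared inputs, making every
#' inter-stage artifact self-describing.
#'
#' @param df data.frame to write.
#' @param path output TSV path.
#' @param stage label of the producing pipeline stage.
#' @param config optional \code{RunConfig}.
#' @param inputs character vector of input file paths to hash.
#' @return invisibly, the path.
#' @export
writeTableTsv <- function(df, path, stage = "unspecified", config = NULL,
                          inputs = character(0)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(stage = stage,
                     columns = names(df),
                     n_rows = nrow(df),
                     config = if (is.null(config)) NULL else unclass(config),
                     input_md5 = as.list(tools::md5sum(
                         inputs[file.exists(inputs)])))
    jsonlite::write_json(manifest, paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(path)
}

#' Read a TSV written by \code{writeTableTsv}
#' @param path TSV path.
#' @return data.frame.
#' @export
readTableTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, header = TRUE, sep = "\t", quote = "",
               stringsAsFactors = FALSE, check.names = FALSE)
}

## Write an igraph back to the edge-list contract.
.write_network <- function(g, path, ...) {
    df <- igraph::as_data_frame(g, what = "edges")
    if (is.null(df$weight)) df$weight <- 1
    writeTableTsv(df[, c("from", "to", "weight")], path, ...)
}
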