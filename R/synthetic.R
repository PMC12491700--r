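## Synthetic cohorts with planted ground truth.  The generator emulates the
## shape of the framework's real inputs (GWAS lead/LD SNPs, QTL and PCHi-C
## link tables, gene annotations, a scale-free interaction network, pathway
## gene sets and a drug-target table) without attempting to mimic real LD
## structure or real pathway topology.

.pad_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Generate a synthetic multi-omic cohort with planted target genes
#'
#' Planted targets receive a genome-wide-significant lead SNP inside their
#' proximity window (P ~ 10^-U(9,20)), strong QTL and PCHi-C links
#' (strength ~ 10^-U(6,12)) and dense high-weight wiring to each other on a
#' preferential-attachment (m = 2) network.  Background loci carry marginally
#' significant leads (P ~ 10^-U(8,9)) and weak links
#' (strength ~ 10^-U(0.5,2)).  \code{signal_strength} interpolates each
#' planted predictor between the background draw (0) and the full planted
#' draw (1), so separation is monotone in it; predictors not listed in
#' \code{signal_predictors} stay at background level for targets.
#'
#' @param n_genes number of genes in the universe.
#' @param n_loci number of GWAS loci (>= n_targets); each locus contributes a
#'   lead SNP and 1-3 LD proxies.
#' @param n_targets number of planted target genes.
#' @param seed integer RNG seed; all output is deterministic given it.
#' @param signal_strength scalar in [0, 1].
#' @param signal_predictors subset of
#'   \code{c("proximity", "qtl", "conformation", "network")} carrying
#'   planted signal ("network" controls the dense planted wiring).
#' @param n_pathways number of gene sets (one contains the planted module).
#' @param out_dir optional directory; when given, every table is also written
#'   in the package's file contracts.
#'
#' @return list with elements \code{gwas}, \code{evidence_qtl},
#'   \code{evidence_pchic}, \code{annotations}, \code{network} (igraph),
#'   \code{gene_sets}, \code{drug_table}, \code{targets} and \code{manifest}
#'   (the truth manifest: planted sets, per-predictor support flags and
#'   generator parameters).
#' @export
genCohort <- function(n_genes = 200L, n_loci = 40L, n_targets = 10L,
                      seed = 1L, signal_strength = 1,
                      signal_predictors = c("proximity", "qtl",
                                            "conformation", "network"),
                      n_pathways = 8L, out_dir = NULL) {
    if (n_targets > n_genes) stop("infeasible sizes: n_targets > n_genes")
    if (n_loci < n_targets) stop("infeasible sizes: n_loci < n_targets")
    if (signal_strength < 0 || signal_strength > 1)
        stop("signal_strength must be in [0, 1]")
    signal_predictors <- match.arg(signal_predictors, several.ok = TRUE)
    set.seed(as.integer(seed))
    s <- signal_strength

    genes <- .pad_ids("G", n_genes)
    gene_len <- 10000L
    spacing <- 100000L
    ann <- data.frame(gene_id = genes, chrom = "chr1",
                      start = seq_len(n_genes) * spacing,
                      end = seq_len(n_genes) * spacing + gene_len - 1L,
                      stringsAsFactors = FALSE)

    targets <- sort(sample(genes, n_targets))
    ## locus placement is itself part of the planted signal: at full strength
    ## every target owns a locus; at zero strength loci land on random genes,
    ## leaving targets exchangeable with background
    pinned <- runif(n_targets) < s
    bg_locus_genes <- sample(setdiff(genes, targets[pinned]),
                             n_loci - sum(pinned))
    locus_genes <- c(targets[pinned], bg_locus_genes)
    is_target_locus <- locus_genes %in% targets

    ## interpolate a -log10 exponent between background and planted draws
    draw_exp <- function(n, lo_bg, hi_bg, lo_sig, hi_sig, strong) {
        bg <- runif(n, lo_bg, hi_bg)
        sig <- runif(n, lo_sig, hi_sig)
        ifelse(strong, s * sig + (1 - s) * bg, bg)
    }

    prox_on <- "proximity" %in% signal_predictors
    lead_exp <- draw_exp(n_loci, 8, 9, 9, 20, is_target_locus & prox_on)

    gwas <- do.call(rbind, lapply(seq_len(n_loci), function(i) {
        gi <- match(locus_genes[i], genes)
        win <- c(ann$start[gi] - 20000L, ann$end[gi] + 20000L)
        lead_pos <- round(runif(1, max(1, win[1]), win[2]))
        lead_id <- sprintf("rs%04d", i * 10L)
        n_proxy <- sample(1:3, 1)
        proxy_r2 <- runif(n_proxy, 0.8, 1)
        proxy_exp <- pmax(7.4, lead_exp[i] - runif(n_proxy, 0, 1.5))
        data.frame(
            snp_id = c(lead_id, sprintf("rs%04d", i * 10L + seq_len(n_proxy))),
            chrom = "chr1",
            pos = c(lead_pos,
                    pmax(1, lead_pos + sample(-15000:15000, n_proxy))),
            p_value = 10^-c(lead_exp[i], proxy_exp),
            lead_id = lead_id,
            r2 = c(1, proxy_r2),
            stringsAsFactors = FALSE)
    }))
    rownames(gwas) <- NULL

    lead_ids <- sprintf("rs%04d", seq_len(n_loci) * 10L)
    make_evidence <- function(kind_on) {
        strong <- is_target_locus & kind_on
        ex <- draw_exp(n_loci, 0.5, 2, 6, 12, strong)
        ## each locus links its lead SNP to its gene, plus a decoy link to a
        ## random other gene at background strength
        decoy <- sample(genes, n_loci, replace = TRUE)
        data.frame(
            snp_id = rep(lead_ids, 2),
            gene_id = c(locus_genes, decoy),
            strength = pmin(1, c(10^-ex, 10^-runif(n_loci, 0.5, 2))),
            stringsAsFactors = FALSE)
    }
    ev_qtl <- make_evidence("qtl" %in% signal_predictors)
    ev_pchic <- make_evidence("conformation" %in% signal_predictors)

    ## scale-free background network; gene labels assigned in random order so
    ## targets are not systematically hubs
    g <- igraph::sample_pa(n_genes, m = 2, directed = FALSE)
    igraph::V(g)$name <- sample(genes)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 0.8)
    if (s > 0 && "network" %in% signal_predictors) {
        ## dense planted wiring: ring over the targets plus random chords
        ring <- cbind(targets, targets[c(2:n_targets, 1)])
        chords <- t(combn(targets, 2))
        chords <- chords[runif(nrow(chords)) < 0.3, , drop = FALSE]
        extra <- rbind(ring, chords)
        g <- igraph::add_edges(g, t(extra),
                               weight = s * runif(nrow(extra), 0.8, 1) +
                                        (1 - s) * runif(nrow(extra), 0.2, 0.8))
        g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
    }

    ## pathway sets with controlled overlap; set 1 holds the planted module
    module_genes <- unique(c(targets,
        sample(setdiff(genes, targets), min(15, n_genes - n_targets))))
    sets <- list(PW01 = sort(module_genes))
    for (k in seq_len(n_pathways - 1L)) {
        base <- sample(genes, min(25, n_genes))
        ## force overlap with the previous set
        prev <- sets[[length(sets)]]
        base <- unique(c(base, sample(prev, min(5, length(prev)))))
        sets[[sprintf("PW%02d", k + 1L)]] <- sort(base)
    }

    ## drug table: half the planted-module genes approved, plus phased decoys
    approved_genes <- sample(module_genes,
                             max(1, floor(length(module_genes) / 2)))
    phased_genes <- sample(setdiff(genes, approved_genes),
                           max(1, floor(n_genes / 20)))
    drug <- rbind(
        data.frame(drug = sprintf("DRUG_A%02d", seq_along(approved_genes)),
                   target = approved_genes, phase = 4L,
                   indication = "other_disease", stringsAsFactors = FALSE),
        data.frame(drug = sprintf("DRUG_P%02d", seq_along(phased_genes)),
                   target = phased_genes,
                   phase = sample(1:3, length(phased_genes), replace = TRUE),
                   indication = "other_disease", stringsAsFactors = FALSE))
    drug$approved <- drug$phase >= max(drug$phase)

    manifest <- list(
        planted_target_genes = targets,
        planted_module_genes = sort(module_genes),
        approved_target_genes = sort(approved_genes),
        predictor_support = setNames(
            c("proximity", "qtl", "conformation") %in% signal_predictors,
            c("proximity", "qtl", "conformation")),
        params = list(n_genes = n_genes, n_loci = n_loci,
                      n_targets = n_targets, seed = as.integer(seed),
                      signal_strength = s,
                      network_model = "preferential_attachment_m2"))

    out <- list(gwas = gwas, evidence_qtl = ev_qtl, evidence_pchic = ev_pchic,
                annotations = ann, network = g, gene_sets = sets,
                drug_table = drug, targets = targets, manifest = manifest)
    if (!is.null(out_dir)) .write_cohort(out, out_dir)
    out
}

.write_cohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    writeTableTsv(cohort$gwas, p("gwas.tsv"), stage = "simulate")
    writeTableTsv(cohort$evidence_qtl[, c("snp_id", "gene_id", "strength")],
                  p("evidence_qtl.tsv"), stage = "simulate")
    writeTableTsv(cohort$evidence_pchic[, c("snp_id", "gene_id", "strength")],
                  p("evidence_pchic.tsv"), stage = "simulate")
    writeTableTsv(cohort$annotations, p("annotations.tsv"), stage = "simulate")
    .write_network(cohort$network, p("network.tsv"), stage = "simulate")
    writeGmt(cohort$gene_sets, p("gene_sets.gmt"))
    writeTableTsv(cohort$drug_table[, c("drug", "target", "phase",
                                        "indication")],
                  p("drug_table.tsv"), stage = "simulate")
    writeLines(cohort$targets, p("targets.txt"))
    jsonlite::write_json(cohort$manifest, p("truth_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(dir)
}

#' Generate a prize graph with a planted high-prize module
#'
#' A preferential-attachment (m = 2) background network in which a connected
#' module of \code{module_size} nodes gets prizes elevated by
#' \code{prize_gap} over the Uniform(0, 1) background, dense internal wiring
#' and high internal edge weights (low costs after the standard
#' weight-to-cost transform).
#'
#' @param n number of nodes.
#' @param module_size planted module size (>= 2, < n).
#' @param prize_gap additive prize elevation of module nodes (>= 0; 0 gives
#'   a null graph with no planted structure).
#' @param seed integer RNG seed.
#' @return list with \code{network} (igraph with edge weights), \code{prizes}
#'   (named numeric) and \code{manifest}.
#' @export
genPrizeGraph <- function(n = 60L, module_size = 10L, prize_gap = 5,
                          seed = 1L) {
    if (module_size < 2) stop("module_size must be >= 2")
    if (module_size >= n) stop("module_size must be < n")
    if (prize_gap < 0) stop("prize_gap must be >= 0")
    set.seed(as.integer(seed))
    g <- igraph::sample_pa(n, m = 2, directed = FALSE)
    igraph::V(g)$name <- .pad_ids("N", n)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 0.6)

    ## connected module: breadth-first prefix from a random start node.
    ## The module reuses existing edges (internal weights are raised, no
    ## edges added) so its degree sequence stays typical of the graph and a
    ## degree-binned permutation null genuinely mixes module and background.
    start <- sample(igraph::V(g), 1)
    bfs_order <- igraph::bfs(g, root = start)$order
    module <- igraph::V(g)$name[as.integer(bfs_order)[seq_len(module_size)]]

    if (prize_gap > 0) {
        el <- igraph::as_edgelist(g)
        internal <- el[, 1] %in% module & el[, 2] %in% module
        w <- igraph::E(g)$weight
        w[internal] <- runif(sum(internal), 0.8, 1)
        igraph::E(g)$weight <- w
    }

    prizes <- setNames(runif(n, 0, 1), igraph::V(g)$name)
    prizes[module] <- prizes[module] + prize_gap

    list(network = g, prizes = prizes,
         manifest = list(planted_module_genes = sort(module),
                         params = list(n = n, module_size = module_size,
                                       prize_gap = prize_gap,
                                       seed = as.integer(seed),
                                       network_model =
                                           "preferential_attachment_m2")))
}
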