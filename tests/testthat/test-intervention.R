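test_that("removal fractions match hand cases and a components oracle", {
    ## path a-b-c: removing b leaves components {a}, {c} -> 2/3
    path <- tiny_graph(cbind(c("a", "b"), c("b", "c")))
    expect_equal(removalEffect(path, "b")$fraction, 2 / 3)
    ## star with 4 leaves: removing the hub -> 4/5
    star <- tiny_graph(cbind("hub", paste0("l", 1:4)))
    rep_hub <- removalEffect(star, "hub")
    expect_equal(rep_hub$fraction, 4 / 5)
    expect_setequal(rep_hub$disconnected, c("hub", paste0("l", 2:4)))
    ## removing nothing on a connected graph
    expect_equal(removalEffect(path)$fraction, 0)
    ## removing everything
    expect_warning(all_gone <- removalEffect(path, c("a", "b", "c")),
                   "every node")
    expect_equal(all_gone$fraction, 1)
    expect_error(removalEffect(path, "zz"), "subset")
    ## brute-force oracle on random graphs
    for (sd in 1:5) {
        set.seed(sd)
        g <- igraph::sample_gnp(12, 0.25)
        igraph::V(g)$name <- paste0("v", 1:12)
        rm_set <- sample(igraph::V(g)$name, 3)
        keep <- setdiff(igraph::V(g)$name, rm_set)
        comp <- igraph::components(igraph::induced_subgraph(g, keep))
        expect_equal(removalEffect(g, rm_set)$fraction,
                     1 - max(comp$csize) / 12)
    }
})

test_that("combinatorial removal ranks exhaustively and monotonically", {
    g <- tiny_graph(cbind(c("a", "b", "c", "c"), c("b", "c", "d", "e")))
    cr <- combinatorialRemoval(g, k_max = 2)
    ## best single removal equals the max over singletons
    singles <- cr$report[cr$report$k == 1, ]
    best_single <- max(vapply(igraph::V(g)$name, function(v)
        removalEffect(g, v)$fraction, numeric(1)))
    expect_equal(max(singles$fraction), best_single)
    ## fraction monotone under superset
    rep_map <- setNames(cr$report$fraction, cr$report$combo)
    for (i in seq_len(nrow(cr$report))) {
        s <- strsplit(cr$report$combo[i], ",")[[1]]
        if (length(s) == 1) {
            supersets <- grep(paste0("\\b", s, "\\b"), cr$report$combo)
            expect_true(all(cr$report$fraction[supersets] >=
                            rep_map[[cr$report$combo[i]]] - 1e-12))
        }
    }
    ## k_max covering V reaches fraction 1
    cr_all <- suppressWarnings(combinatorialRemoval(g, k_max = 5))
    expect_equal(max(cr_all$report$fraction), 1)
    ## incidence table is upset-style
    expect_equal(nrow(cr$incidence), nrow(cr$report))
    expect_true(all(igraph::V(g)$name %in% names(cr$incidence)))
    ## guard against blow-up
    big <- igraph::make_ring(60)
    igraph::V(big)$name <- paste0("v", 1:60)
    expect_error(combinatorialRemoval(big, k_max = 6), "blow-up")
})

test_that("drug enrichment reproduces the 2x2 arithmetic", {
    universe <- sprintf("g%04d", 1:2000)
    crosstalk <- universe[1:51]
    approved <- c(universe[1:9], universe[100:190])    # 100 targets, 9 in
    dt <- data.frame(drug = paste0("d", seq_along(approved)),
                     target = approved, phase = 4,
                     indication = "x", approved = TRUE,
                     stringsAsFactors = FALSE)
    de <- drugEnrichment(crosstalk, dt, universe)
    expect_equal(de$enrichment$overlap, 9L)
    expect_equal(de$enrichment$odds_ratio, (9 * 1858) / (42 * 91),
                 tolerance = 1e-12)
    expect_equal(de$enrichment$p, brute_hyper_tail(9, 100, 2000, 51),
                 tolerance = 1e-12)
    ## indication incidence covers exactly the overlapping genes
    expect_setequal(unique(de$indications$gene), universe[1:9])
    ## overlap at the independence expectation gives OR near 1
    set.seed(1)
    uni2 <- sprintf("u%03d", 1:400)
    cross2 <- uni2[1:100]                     # 1/4 of the universe
    app2 <- c(uni2[1:25], uni2[101:175])      # 100 targets, 25 in (expected)
    dt2 <- data.frame(drug = "d", target = app2, phase = 4,
                      indication = "x", approved = TRUE)
    de2 <- drugEnrichment(cross2, dt2, uni2)
    expect_equal(de2$enrichment$odds_ratio, 1, tolerance = 0.05)
    expect_error(drugEnrichment(crosstalk, dt, paste0("zzz", 1:5)),
                 "subset|approved")
})

test_that("Fisher P equals the exhaustive tail and the stats oracle", {
    ## enumeration for small universes
    for (case in list(c(30, 8, 10, 4), c(20, 5, 6, 2), c(50, 12, 9, 6))) {
        N <- case[1]; K <- case[2]; n <- case[3]; k <- case[4]
        uni <- paste0("g", 1:N)
        enr <- setEnrichment(uni[1:n],
                             list(s = c(uni[1:k], uni[(n + 1):(n + K - k)])),
                             uni)
        expect_equal(enr$p, brute_hyper_tail(k, K, N, n), tolerance = 1e-10)
        ## independent cross-check: one-sided fisher.test
        ft <- fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2),
                          alternative = "greater")
        expect_equal(enr$p, ft$p.value, tolerance = 1e-10)
    }
})

test_that("spin-glass annealing splits the two-clique benchmark", {
    g <- two_clique_graph()
    oracle <- brute_best_bipartition(g)
    mp <- spinglassModules(g, seed = 42)
    expect_length(unique(mp$membership), 2)
    ## matches the exhaustively verified optimal bipartition
    expect_equal(unname(mp$membership[paste0("n", 1:5)]),
                 rep(mp$membership[["n1"]], 5))
    expect_equal(unname(mp$membership[paste0("n", 6:10)]),
                 rep(mp$membership[["n6"]], 5))
    expect_equal(mp$hamiltonian, oracle$H, tolerance = 1e-9)
    ## complete graph: one module
    kg <- igraph::make_full_graph(6)
    igraph::V(kg)$name <- paste0("k", 1:6)
    mp_k <- spinglassModules(kg, seed = 1)
    expect_length(unique(mp_k$membership), 1)
    ## determinism per seed
    mp2 <- spinglassModules(g, seed = 42)
    expect_identical(mp$membership, mp2$membership)
    expect_error(spinglassModules(igraph::make_empty_graph(0)), "empty")
})

test_that("module enrichment separates approved and phased target groups", {
    universe <- sprintf("g%03d", 1:120)
    moduleA <- universe[1:20]        # loaded with approved targets
    moduleB <- universe[21:40]       # no drug targets
    dt <- data.frame(drug = paste0("d", 1:30),
                     target = c(universe[1:15], universe[60:74]),
                     phase = c(rep(4, 15), rep(2, 15)),
                     indication = "x", stringsAsFactors = FALSE)
    dt$approved <- dt$phase >= max(dt$phase)
    part <- structure(list(
        membership = setNames(c(rep(1L, 20), rep(2L, 20)),
                              c(moduleA, moduleB)),
        labels = c("PM1", "PM2"), hamiltonian = 0, gamma_rb = 1,
        trace = list()), class = "ModulePartition")
    sets <- list(pw1 = universe[1:25], pw2 = universe[80:100])
    me <- moduleEnrichment(part, sets, dt, universe)
    a1 <- me[me$module == "PM1" & me$category == "approved", ]
    expect_gt(a1$odds_ratio, 1)
    expect_lt(a1$p, 0.05)
    a2 <- me[me$module == "PM2" & me$category == "approved", ]
    expect_lt(a2$odds_ratio, 1)      # Haldane-corrected, zero overlap
    ## pathway FDR is BH within module and category
    pw_rows <- me[me$module == "PM1" & me$category == "pathway", ]
    expect_equal(pw_rows$fdr, p.adjust(pw_rows$p, "BH"))
})
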