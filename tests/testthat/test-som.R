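test_that("supra-hexagonal lattice has 3r^2 - 3r + 1 nodes and hex adjacency", {
    expect_equal(nrow(mapCoords(buildLattice(1))), 1)
    expect_equal(nrow(mapCoords(buildLattice(2))), 7)
    expect_equal(nrow(mapCoords(buildLattice(5))), 61)
    expect_error(buildLattice(0), "r must be")
    map <- buildLattice(3)
    ## centre node has 6 neighbours, rim nodes have 3 or 4
    expect_length(map@neighbours[[1]], 6)
    rim <- which(map@ring == 3)
    expect_true(all(lengths(map@neighbours[rim]) %in% 3:4))
    ## ring sizes 1, 6, 12
    expect_equal(as.integer(table(map@ring)), c(1L, 6L, 12L))
    ## unit spacing between adjacent nodes
    d <- as.matrix(dist(mapCoords(map)))
    expect_equal(unique(round(d[cbind(rep(1:19, lengths(map@neighbours)),
                                      unlist(map@neighbours))], 6)), 1)
})

test_that("training collapses to a single attractor and reduces error", {
    v <- c(2, -1)
    d <- matrix(rep(v, each = 100), 100, 2)
    rownames(d) <- paste0("g", 1:100)
    map <- trainSom(buildLattice(3, 2), d)
    expect_true(all(abs(sweep(codebook(map), 2, v)) < 1e-3))
    ## quantization error never increases on varied fixtures
    for (sd in 1:3) {
        set.seed(sd)
        dd <- matrix(rnorm(120), 60, 2)
        rownames(dd) <- paste0("g", 1:60)
        m <- trainSom(buildLattice(3, 2), dd)
        expect_lte(m@qe[2], m@qe[1])
    }
    ## determinism under a fixed schedule seed
    set.seed(77)
    dd <- matrix(rnorm(80), 40, 2); rownames(dd) <- paste0("g", 1:40)
    lat <- buildLattice(3, 2)
    m1 <- trainSom(lat, dd, somSchedule(lat, rng_seed = 5))
    m2 <- trainSom(lat, dd, somSchedule(lat, rng_seed = 5))
    expect_identical(codebook(m1), codebook(m2))
    expect_error(trainSom(buildLattice(2, 2),
                          matrix(numeric(0), 0, 2)), "empty")
})

test_that("gene assignment is the exhaustive nearest-codebook scan", {
    set.seed(4)
    d <- matrix(rnorm(100), 50, 2); rownames(d) <- paste0("g", 1:50)
    map <- trainSom(buildLattice(3, 2), d)
    a <- mapGenes(map, d)
    cb <- codebook(map)
    for (i in seq_len(nrow(d))) {
        d2 <- rowSums(sweep(cb, 2, d[i, ])^2)
        expect_equal(unname(a[i]), unname(which.min(d2)))
    }
    ## exact codebook match lands on that node
    probe <- cb[7, , drop = FALSE]; rownames(probe) <- "probe"
    expect_equal(unname(mapGenes(map, probe)), 7L)
    expect_error(mapGenes(map, matrix(0, 1, 5)), "dimension mismatch")
})

test_that("kernel is 1 at the winner and decays with lattice distance", {
    map <- buildLattice(3)
    co <- mapCoords(map)
    sigma <- 1.5
    ld2 <- rowSums(sweep(co, 2, co[1, ])^2)
    h <- exp(-ld2 / (2 * sigma^2))
    expect_equal(unname(h[1]), 1)
    ord <- order(ld2)
    expect_true(all(diff(h[ord]) <= 1e-12))
})

test_that("partitioning recovers planted clouds and stays lattice-connected", {
    set.seed(1)
    d <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 6), 50, 2))
    rownames(d) <- paste0("g", 1:100)
    map <- trainSom(buildLattice(4, 2), d)
    part <- partitionMap(map, 2)
    cg <- clusterGenes(part, mapGenes(map, d))
    cloud1 <- paste0("g", 1:50)
    expect_true(setequal(cg[[1]], cloud1) || setequal(cg[[2]], cloud1))
    ## k = 1: everything in one cluster
    p1 <- partitionMap(map, 1)
    expect_equal(unname(unique(p1$cluster)), 1L)
    ## every cluster is lattice-connected for every feasible k
    max_k <- 3
    for (k in 1:max_k) {
        pk <- tryCatch(partitionMap(map, k), error = function(e) NULL)
        if (is.null(pk)) next
        for (cl in unique(pk$cluster)) {
            nodes <- which(pk$cluster == cl)
            adj <- outer(nodes, nodes, Vectorize(function(i, j)
                j %in% map@neighbours[[i]]))
            sub <- igraph::graph_from_adjacency_matrix(adj * 1,
                mode = "undirected")
            expect_true(igraph::is_connected(sub))
        }
    }
    ## topology preservation: lattice distance correlates with codebook
    ## distance across node pairs
    ld <- as.vector(dist(mapCoords(map)))
    cd <- as.vector(dist(codebook(map)))
    expect_gt(cor(ld, cd, method = "spearman"), 0)
})

test_that("cluster enrichment reproduces hypergeometric closed forms", {
    universe <- paste0("g", 1:100)
    sets <- list(hit = paste0("g", 1:10), miss = paste0("g", 91:95))
    query <- paste0("g", 1:10)
    ## overlap 5 case checked against the hand Z value elsewhere; here the
    ## full-overlap case and the BH monotonicity
    enr <- setEnrichment(query, sets, universe)
    expect_equal(enr$overlap, c(10L, 0L))
    expect_equal(enr$p[1], brute_hyper_tail(10, 10, 100, 10),
                 tolerance = 1e-12)
    ## zero-overlap set gets OR < 1 after Haldane correction
    expect_lt(enr$odds_ratio[2], 1)
    expect_true(all(enr$fdr >= enr$p))
    ## BH never inverts P order
    ord <- order(enr$p)
    expect_true(all(diff(enr$fdr[ord]) >= -1e-12))
    expect_error(setEnrichment(query, sets, character(0)), "empty universe")
    expect_error(setEnrichment("zz", sets, universe), "subset")
})
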