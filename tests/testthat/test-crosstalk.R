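test_that("prize graph construction maps ratings to prizes, weights to costs", {
    g <- tiny_graph(cbind(c("a", "b"), c("b", "c")), weights = c(1, 0.5))
    pg <- makePrizeGraph(g, c(a = 5, c = 2, zz = 9))
    expect_equal(igraph::V(pg)$prize[match(c("a", "b", "c"),
                                           igraph::V(pg)$name)],
                 c(5, 0, 2))
    ## strongest interaction gets the floor cost
    expect_equal(sort(igraph::E(pg)$cost), c(0.01, 0.5))
    expect_error(makePrizeGraph(g, c(a = -1)), "non-negative")
})

test_that("tree search returns trees and respects hand-checked optima", {
    ## triangle with prizes (5, 1, 5), unit costs: optimum 9
    tri <- tiny_graph(cbind(c("a", "a", "b"), c("b", "c", "c")))
    igraph::V(tri)$prize <- c(a = 5, b = 1, c = 5)[igraph::V(tri)$name]
    igraph::E(tri)$cost <- 1
    res <- pcst(tri, lambda = 1)
    expect_equal(res@objective, 9)
    expect_equal(nrow(crosstalkEdges(res)), length(crosstalkGenes(res)) - 1)
    ## single high-prize node stands alone when edges are dear
    iso <- tiny_graph(cbind("a", "b"))
    igraph::V(iso)$prize <- c(a = 3, b = 0.1)[igraph::V(iso)$name]
    igraph::E(iso)$cost <- 10
    res1 <- pcst(iso, lambda = 1)
    expect_equal(crosstalkGenes(res1), "a")
    expect_equal(res1@objective, 3)
    ## all-zero prizes warn and return a singleton
    igraph::V(iso)$prize <- 0
    expect_warning(res0 <- pcst(iso, 1), "prizes are 0")
    expect_length(crosstalkGenes(res0), 1)
})

test_that("heuristic stays within 10% of the brute-force optimum", {
    worst <- 1
    for (i in 1:60) {
        g <- random_prize_graph(n = 5 + (i %% 8), seed = 1000 + i)
        lam <- 0.5 + (i %% 4) / 2
        h <- pcst(g, lam)@objective
        b <- brute_pcst(g, lam)
        expect_lte(h, b + 1e-9)       # heuristic never beats the oracle
        if (b > 0) worst <- min(worst, h / b)
    }
    expect_gte(worst, 0.9)
})

test_that("objective is monotone under prize increases", {
    g <- random_prize_graph(10, seed = 77)
    base <- pcst(g, 1)@objective
    igraph::V(g)$prize <- igraph::V(g)$prize + 1
    expect_gte(pcst(g, 1)@objective, base)
})

test_that("size-constrained search shrinks with lambda and hits the module", {
    pg <- genPrizeGraph(n = 60, module_size = 10, prize_gap = 5, seed = 7)
    gg <- makePrizeGraph(pg$network, pg$prizes)
    ## sizes non-increasing across a lambda sweep
    sizes <- vapply(c(0.01, 0.1, 1, 10, 100), function(l)
        length(crosstalkGenes(pcst(gg, l))), integer(1))
    expect_true(all(diff(sizes) <= 0))
    ## the planted 10-node module is recovered exactly
    res <- pcstWithSize(gg, 10)
    expect_setequal(crosstalkGenes(res), pg$manifest$planted_module_genes)
    expect_equal(res@target_n, 10)
    ## target_n = 1 returns the highest-prize node
    res1 <- pcstWithSize(gg, 1)
    expect_equal(crosstalkGenes(res1),
                 names(which.max(pg$prizes)))
    expect_error(pcstWithSize(gg, 0), "target_n")
})

test_that("permutation P lives on the +1-corrected grid and flags the module", {
    pg <- genPrizeGraph(n = 60, module_size = 10, prize_gap = 5, seed = 3)
    gg <- makePrizeGraph(pg$network, pg$prizes)
    res <- pcstWithSize(gg, 10)
    out <- permutationTest(gg, res, n_perm = 49, seed = 11)
    expect_equal(out@pvalue, 1 / 50)
    ## n_perm = 1 with a certain hit gives P = 1: degenerate flat prizes
    gflat <- gg
    igraph::V(gflat)$prize <- 1
    rflat <- pcst(gflat, 1e-4)
    pflat <- permutationTest(gflat, rflat, n_perm = 1, seed = 1)
    expect_equal(pflat@pvalue, 1)
    expect_error(permutationTest(gg, res, n_perm = 0), "n_perm")
})

test_that("pathway view keeps significant sets and spanning-tree edges", {
    universe <- sprintf("g%03d", 1:200)
    crossg <- universe[1:51]
    sets <- list(
        big = universe[1:35],              # 35 crosstalk members
        mid = c(universe[10:31], universe[150:170]),
        small = c(universe[25:40], universe[100:120]),
        out = universe[150:190])           # no crosstalk member
    res <- new("CrosstalkResult", nodes = crossg,
               edges = data.frame(from = crossg[-1], to = crossg[-51],
                                  cost = 0.1),
               prizes = setNames(rep(1, 51), crossg), objective = 51 - 5,
               lambda = 1, pvalue = NA_real_, target_n = NA_real_)
    pv <- pathwayView(res, sets, universe, alpha = 0.05, by = "p")
    expect_true(all(c("big", "mid", "small") %in% pv$nodes$pathway))
    expect_false("out" %in% pv$nodes$pathway)
    ## node size = in-crosstalk member count
    expect_equal(pv$nodes$size[pv$nodes$pathway == "big"], 35L)
    ## spanning tree on 3 nodes keeps the 2 heaviest edges
    expect_equal(nrow(pv$edges), 2)
    shared_bm <- length(intersect(intersect(sets$big, crossg),
                                  intersect(sets$mid, crossg)))
    expect_true(shared_bm %in% pv$edges$shared)
    ## no significant pathway -> empty view with warning
    expect_warning(
        pv0 <- pathwayView(res, list(out = sets$out), universe, by = "p"),
        "no significant pathway")
    expect_equal(nrow(pv0$nodes), 0)
})
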