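test_that("affinity-to-P conversion is complementary and rank-symmetric", {
    af <- cbind(p1 = c(g1 = 0.5, g2 = 0.3, g3 = 0.15, g4 = 0.05))
    pm <- new("PredictorMatrix", affinity = af,
              seeded = af > 0.2, gamma = 0.3)
    conv <- affinityToP(pm)
    ## top gene gets 1/K, bottom gets 1
    expect_equal(unname(conv$P[, 1]), c(0.25, 0.5, 0.75, 1))
    ## reversing the column reverses the P order
    af_rev <- cbind(p1 = rev(af[, 1]))
    rownames(af_rev) <- rownames(af)
    pm_rev <- new("PredictorMatrix", affinity = af_rev,
                  seeded = af_rev > 0.2, gamma = 0.3)
    expect_equal(unname(affinityToP(pm_rev)$P[, 1]), c(1, 0.75, 0.5, 0.25))
    ## ties: constant column warns and sets all P to 1
    af_c <- cbind(p1 = rep(0.25, 4)); rownames(af_c) <- rownames(af)
    pm_c <- new("PredictorMatrix", affinity = af_c,
                seeded = af_c > 0, gamma = 0.3)
    expect_warning(conv_c <- affinityToP(pm_c), "constant")
    expect_equal(unname(conv_c$P[, 1]), rep(1, 4))
    ## zero cells are non-informative
    af_z <- cbind(p1 = c(g1 = 0.6, g2 = 0.4, g3 = 0))
    pm_z <- new("PredictorMatrix", affinity = af_z,
                seeded = af_z > 0, gamma = 0.3)
    conv_z <- affinityToP(pm_z)
    expect_true(is.na(conv_z$P["g3", 1]))
    expect_equal(unname(conv_z$J), c(1L, 1L, 0L))
})

test_that("Fisher combination matches the chi-squared survival closed form", {
    ## J = 1 identity
    expect_equal(combineFisher(0.05)$cp, 0.05, tolerance = 1e-12)
    ## J = 2 closed form exp(-x/2) (1 + x/2)
    r <- combineFisher(c(0.05, 0.05))
    expect_equal(r$x, -4 * log(0.05), tolerance = 1e-12)
    expect_equal(r$cp, exp(-r$x / 2) * (1 + r$x / 2), tolerance = 1e-12)
    ## all P = 1
    r1 <- combineFisher(c(1, 1, 1))
    expect_equal(r1$x, 0)
    expect_equal(r1$cp, 1)
    ## closed forms at df 2, 4, 6
    for (J in 1:3) {
        p <- runif(J, 0.01, 0.99)
        x <- -2 * sum(log(p))
        closed <- exp(-x / 2) * sum((x / 2)^(0:(J - 1)) /
                                    factorial(0:(J - 1)))
        expect_equal(combineFisher(p)$cp, closed, tolerance = 1e-10)
    }
    expect_error(combineFisher(numeric(0)), "empty")
})

test_that("logit combination has symmetric null and antisymmetry", {
    expect_equal(combineLogistic(c(0.5, 0.5, 0.5))$cp, 0.5)
    ## complement row gives 1 - CP
    p <- c(0.1, 0.3, 0.8)
    expect_equal(combineLogistic(p)$cp + combineLogistic(1 - p)$cp, 1,
                 tolerance = 1e-12)
    ## strong evidence beats its strongest component
    expect_lt(combineLogistic(c(0.01, 0.01))$cp, 0.01)
    ## oracle: CP equals the numerically integrated t tail
    r <- combineLogistic(c(0.02, 0.2))
    df <- 5 * 2 + 4
    tail_num <- integrate(function(u) dt(u, df), r$x, Inf,
                          rel.tol = 1e-10)$value
    expect_equal(r$cp, tail_num, tolerance = 1e-8)
    expect_error(combineLogistic(c(0.5, 1)), "strictly inside")
})

test_that("order-statistic combination follows Beta closed forms", {
    ## paper-literal maximum order statistic: CP = x^J
    r <- combineOrder(c(0.2, 0.5))
    expect_equal(r$x, 0.5)
    expect_equal(r$cp, 0.25, tolerance = 1e-12)
    expect_equal(combineOrder(0.37)$cp, 0.37, tolerance = 1e-12)
    ## generalised k-th order statistic against Beta(k, J - k + 1)
    rk <- combineOrder(c(0.2, 0.5), order_k = 1)
    expect_equal(rk$x, 0.2)
    expect_equal(rk$cp, 1 - (1 - 0.2)^2, tolerance = 1e-12)
    expect_error(combineOrder(c(0.2, 0.5), order_k = 3), "out of range")
})

test_that("every combination method is monotone in the P-row", {
    set.seed(31)
    for (i in 1:25) {
        J <- sample(2:5, 1)
        p <- runif(J, 0.05, 0.95)
        q <- pmax(1e-6, p - runif(J, 0, 0.04))   # elementwise smaller
        for (f in list(combineFisher, combineLogistic, combineOrder))
            expect_lte(f(q)$cp, f(p)$cp + 1e-12)
    }
})

test_that("ratings span [0, 10], rank deterministically, ignore log base", {
    log_cp <- log(c(gA = 1e-6, gB = 1e-3, gC = 0.5))
    pt <- ratePriorities(names(log_cp), unname(log_cp), method = "order")
    tb <- priorityTable(pt)
    expect_equal(tb$rating[tb$gene == "gA"], 10)
    expect_equal(tb$rating[tb$gene == "gC"], 0)
    expect_equal(tb$rating[tb$gene == "gB"], 4.736, tolerance = 1e-3)
    expect_equal(sort(tb$rank), 1:3)
    expect_equal(rankedGenes(pt), c("gA", "gB", "gC"))
    ## tie-break is lexicographic on gene id
    pt2 <- ratePriorities(c("zz", "aa", "mm"), log(c(0.5, 0.5, 1e-4)))
    expect_equal(rankedGenes(pt2), c("mm", "aa", "zz"))
    expect_error(ratePriorities(c("a", "b"), log(c(0.1, 0.1))),
                 "degenerate rating range")
    ## full pipeline rating contract on a synthetic cohort
    co <- genCohort(n_genes = 80, n_loci = 20, n_targets = 5, seed = 2)
    for (m in c("fisher", "logistic", "order")) {
        res <- suppressMessages(prioritiseCohort(co,
            runConfig(combine_method = m)))
        r <- priorityTable(res$priority)$rating
        expect_equal(min(r), 0)
        expect_equal(max(r), 10)
    }
})
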