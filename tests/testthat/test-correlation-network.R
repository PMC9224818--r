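test_that("Pearson edges match hand and stats:: oracles", {
    x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
    V <- cbind(a = x, b = 2 * x, c = -x + 0.5)
    co <- raw_cohort(V, 5)
    e <- pairwiseCorrelations(co, group = "combined", loo_fdr = FALSE)
    key <- paste(e$var_a, e$var_b)
    expect_equal(e$r[key == "a b"], 1.0)
    expect_equal(e$r[key == "a c"], -1.0)

    V2 <- cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4),
                z = c(2, 1, 4, 3))
    co2 <- raw_cohort(V2, 2)
    e2 <- pairwiseCorrelations(co2, group = "combined", loo_fdr = FALSE)
    expect_equal(e2$r[e2$var_a == "x" & e2$var_b == "y"], 0.8)
    ct <- cor.test(V2[, "x"], V2[, "y"])
    i <- e2$var_a == "x" & e2$var_b == "y"
    expect_equal(e2$p_value[i], ct$p.value)

    # symmetry: variable order does not change the edge set
    e2b <- pairwiseCorrelations(co2, variables = c("z", "y", "x"),
                                group = "combined", loo_fdr = FALSE)
    k1 <- paste(pmin(e2$var_a, e2$var_b), pmax(e2$var_a, e2$var_b), round(e2$r, 12))
    k2 <- paste(pmin(e2b$var_a, e2b$var_b), pmax(e2b$var_a, e2b$var_b), round(e2b$r, 12))
    expect_setequal(k1, k2)
})

test_that("pairwise complete-case handling gives per-pair n", {
    set.seed(5)
    V <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    V[1:2, 1] <- NA
    co <- raw_cohort(V, 10)
    e <- pairwiseCorrelations(co, group = "combined", loo_fdr = FALSE)
    expect_equal(e$n_pairs[e$var_a == "a" & e$var_b == "b"], 18)
    expect_equal(e$n_pairs[e$var_a == "b" & e$var_b == "c"], 20)
    ok <- complete.cases(V[, c("a", "b")])
    expect_equal(e$r[e$var_a == "a" & e$var_b == "b"],
                 cor(V[ok, "a"], V[ok, "b"]))
})

test_that("gates filter edges and are monotone in r_min", {
    edges <- data.frame(var_a = c("a", "a", "b"), var_b = c("b", "c", "c"),
                        r = c(0.2, 0.9, -0.5),
                        p_value = c(0.5, 1e-6, 0.01),
                        fdr = c(0.6, 0.01, 0.05),
                        n_pairs = c(10, 10, 10), group = "case")
    net <- buildNetwork(edges)
    expect_equal(nrow(networkEdges(net)), 2)
    all_low <- buildNetwork(transform(edges, r = 0.2))
    expect_equal(nrow(networkEdges(all_low)), 0)
    one <- buildNetwork(edges, r_min = 0.6)
    expect_equal(networkEdges(one)$var_b, "c")
    # monotone: every edge surviving a higher gate survives the lower one
    for (rm in c(0.35, 0.5, 0.7, 0.95)) {
        hi <- networkEdges(buildNetwork(edges, r_min = rm))
        lo <- networkEdges(buildNetwork(edges, r_min = rm - 0.1))
        expect_true(all(paste(hi$var_a, hi$var_b) %in%
                        paste(lo$var_a, lo$var_b)))
    }
})

test_that("network contrast counts shared and unique pairs", {
    edges <- function(df) buildNetwork(df, r_min = 0, p_max = 1, fdr_max = 1)
    e1 <- data.frame(var_a = c("a", "b"), var_b = c("b", "c"),
                     r = c(0.5, 0.6), p_value = 0.001, fdr = 0.01,
                     n_pairs = 9, group = "case")
    e2 <- data.frame(var_a = c("a", "c"), var_b = c("b", "d"),
                     r = c(0.4, -0.7), p_value = 0.001, fdr = 0.01,
                     n_pairs = 9, group = "control")
    ct <- compareNetworks(edges(e1), edges(e2))
    expect_equal(ct$n_shared, 1)
    expect_equal(ct$n_case_only, 1)
    expect_equal(ct$n_control_only, 1)
    expect_equal(ct$n_control_only_directed, 2)
    expect_equal(ct$shared_same_sign, 1)
    ident <- compareNetworks(edges(e1), edges(transform(e1, group = "control")))
    expect_equal(ident$n_shared, 2)
    expect_equal(ident$n_case_only + ident$n_control_only, 0)
    disjoint <- compareNetworks(edges(e1),
                                edges(data.frame(var_a = "x", var_b = "y",
                                                 r = 0.9, p_value = 0, fdr = 0,
                                                 n_pairs = 9, group = "control")))
    expect_equal(disjoint$n_shared, 0)
})

test_that("network export writes SIF and round-trippable edge tables", {
    e <- data.frame(var_a = c("a", "b"), var_b = c("b", "c"),
                    r = c(0.5, -0.6), p_value = c(1e-4, 1e-3),
                    fdr = c(0.01, 0.02), n_pairs = c(9, 9), group = "case")
    net <- buildNetwork(e, r_min = 0.35, p_max = 0.05, fdr_max = 0.1)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    sif <- withr::local_tempfile(fileext = ".sif")
    exportNetwork(net, tsv, "edges")
    exportNetwork(net, sif, "sif")
    back <- read.delim(tsv)
    expect_equal(back$weight, networkEdges(net)$r)
    expect_equal(nrow(back), 2)
    expect_identical(readLines(sif), c("a\tpp\tb", "b\tpn\tc"))

    empty <- buildNetwork(e, r_min = 0.99)
    exportNetwork(empty, tsv, "edges")
    expect_equal(nrow(read.delim(tsv)), 0)
    exportNetwork(empty, sif, "sif")
    expect_identical(readLines(sif), character(0))

    # display threshold trims the export, not the network
    exportNetwork(net, tsv, "edges", r_display_min = 0.55)
    expect_equal(nrow(read.delim(tsv)), 1)
    expect_equal(nrow(networkEdges(net)), 2)
})

test_that("null variable pairs rarely pass all three gates", {
    frac <- numeric(25)
    for (r in seq_len(25)) {
        co <- null_cohort(n_case = 50, n_control = 49, n_vars = 12,
                          seed = 900 + r)
        e <- pairwiseCorrelations(co, group = "combined")
        net <- buildNetwork(e)
        frac[r] <- nrow(networkEdges(net)) / nrow(e)
    }
    expect_lte(mean(frac), 0.01)
})

test_that("a planted block is recovered and the group asymmetry detected", {
    spec <- cohortSpec(n_case = 55, n_control = 44, n_vars = 10,
                       planted = NULL,
                       blocks_case = list(list(vars = 1:3, rho = 0.6)),
                       blocks_control = list(list(vars = 1:3, rho = 0.6),
                                             list(vars = 4:8, rho = 0.6)),
                       marginal_families = "normal", case_sd_ratio = NULL,
                       missing_vars = NULL, missing_rate = 0, seed = 77)
    co <- generateCohort(spec)
    nets <- lapply(c("case", "control"), function(g)
        buildNetwork(pairwiseCorrelations(co, group = g), nodes = varNames(co)))
    ct <- compareNetworks(nets[[1]], nets[[2]])
    expect_gt(ct$n_control_only, ct$n_case_only)
    # the extra control block's edges dominate the control-unique set
    expect_gte(sum(grepl("var_00[4-8]~var_00[4-8]", ct$control_only)), 7)
})
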