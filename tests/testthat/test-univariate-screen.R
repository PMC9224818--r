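cfg <- screenConfig()

test_that("test selection routes each constructed pair to its branch", {
    # both normal, equal spread -> equal-variance t-test
    a <- qnorm(ppoints(30)); b <- qnorm(ppoints(30)) + 1
    expect_identical(selectTest(a, b, cfg), "t_equal_var")

    # both normal, SDs 1 vs 4 -> Welch; the F-test itself is the oracle
    a <- qnorm(ppoints(30)); b <- qnorm(ppoints(30)) * 4
    expect_lt(var.test(a, b)$p.value, 0.05)
    expect_identical(selectTest(a, b, cfg), "welch")

    # same skewed shape, no location difference -> Mann-Whitney directly
    a <- qexp(ppoints(50)); b <- qexp(ppoints(50))
    expect_identical(selectTest(a, b, cfg), "mann_whitney")

    # same shape, large shift: raw KS rejects, centered KS does not
    a <- qexp(ppoints(50)); b <- qexp(ppoints(50)) + 5
    expect_identical(selectTest(a, b, cfg), "mean_adjusted_ks_then_mw")

    # different shapes with equal means: centered KS still rejects
    a <- qexp(ppoints(50)); b <- qnorm(ppoints(50), mean = 1, sd = 0.1)
    ks_centered <- suppressWarnings(
        ks.test(a - mean(a), b - mean(b), exact = FALSE)$p.value)
    expect_lt(ks_centered, 0.05)
    expect_identical(selectTest(a, b, cfg), "mean_adjusted_ks_then_welch")
})

test_that("routing is total and deterministic on random inputs", {
    kinds <- c("t_equal_var", "welch", "mann_whitney",
               "mean_adjusted_ks_then_mw", "mean_adjusted_ks_then_welch")
    set.seed(101)
    for (i in 1:50) {
        gen <- sample(3, 2, replace = TRUE)
        mk <- function(g, n) switch(g, rnorm(n), rexp(n), rt(n, 2))
        a <- mk(gen[1], sample(5:40, 1))
        b <- mk(gen[2], sample(5:40, 1))
        k1 <- selectTest(a, b, cfg)
        expect_true(k1 %in% kinds)
        expect_identical(selectTest(a, b, cfg), k1)
    }
})

test_that("degenerate samples raise the skip condition", {
    expect_error(selectTest(c(1, 2), c(1, 2, 3), cfg),
                 class = "metabopanels_degenerate")
    expect_error(selectTest(rep(3, 10), rnorm(10), cfg),
                 class = "metabopanels_degenerate")
})

test_that("runTest matches the standard tests and the exact MW example", {
    # exact rank enumeration: U = 0 over C(6,3) = 20 arrangements
    expect_equal(runTest(c(1, 2, 3), c(4, 5, 6), "mann_whitney"), 0.1)
    # symmetry
    expect_equal(runTest(c(4, 5, 6), c(1, 2, 3), "mann_whitney"), 0.1)
    # identical samples: midranks give U at its mean -> p = 1
    expect_equal(runTest(1:10, 1:10, "mann_whitney"), 1)
    expect_gt(runTest(1:10 + 0.0, 1:10 + 0.0, "t_equal_var"), 0.99)

    set.seed(7)
    for (i in 1:25) {
        a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), sd = 2)
        expect_equal(runTest(a, b, "t_equal_var"),
                     t.test(a, b, var.equal = TRUE)$p.value)
        expect_equal(runTest(a, b, "welch"), t.test(a, b)$p.value)
        exact <- max(length(a), length(b)) <= 20
        expect_equal(runTest(a, b, "mann_whitney"),
                     wilcox.test(a, b, exact = exact,
                                 correct = TRUE)$p.value)
    }
    # mean-adjusted variants use the original samples
    a <- rexp(30); b <- rexp(25) + 3
    expect_equal(runTest(a, b, "mean_adjusted_ks_then_mw"),
                 runTest(a, b, "mann_whitney"))
    expect_equal(runTest(a, b, "mean_adjusted_ks_then_welch"),
                 runTest(a, b, "welch"))
})

test_that("AUROC equals the all-pairs oracle and folds with direction", {
    out <- computeAuroc(c(4, 5, 6), c(1, 2, 3))
    expect_equal(out$auroc, 1.0)
    expect_identical(out$direction, "case_higher")
    expect_equal(computeAuroc(c(2, 4), c(1, 3))$auroc, 0.75)
    tie <- computeAuroc(c(1, 2), c(1, 2))
    expect_equal(tie$auroc, 0.5)
    expect_identical(tie$direction, "case_higher")

    set.seed(11)
    for (i in 1:100) {
        case <- sample(1:8, sample(3:20, 1), replace = TRUE)
        control <- sample(1:8, sample(3:20, 1), replace = TRUE)
        out <- computeAuroc(case, control)
        a <- auroc_pairs_oracle(case, control)
        expect_identical(out$raw, a)
        expect_identical(out$auroc, max(a, 1 - a))
    }
})

test_that("leave-one-out FDR matches an independently coded oracle", {
    co <- planted_cohort(n_case = 15, n_control = 12, n_vars = 5,
                         shifts = 2, seed = 21)
    V <- cohortValues(co)
    case <- isCase(co)
    # independent route: stats:: wrappers + p.adjust, same tree
    route_p <- function(a, b) {
        normal <- shapiro.test(a)$p.value > 0.05 &&
            shapiro.test(b)$p.value > 0.05
        if (normal) {
            eq <- var.test(a, b)$p.value > 0.05
            return(t.test(a, b, var.equal = eq)$p.value)
        }
        raw <- suppressWarnings(ks.test(a, b, exact = FALSE)$p.value)
        if (raw > 0.05)
            return(wilcox.test(a, b, exact = max(length(a), length(b)) <= 20,
                               correct = TRUE)$p.value)
        cen <- suppressWarnings(ks.test(a - mean(a), b - mean(b),
                                        exact = FALSE)$p.value)
        if (cen > 0.05)
            wilcox.test(a, b, exact = max(length(a), length(b)) <= 20,
                        correct = TRUE)$p.value
        else t.test(a, b)$p.value
    }
    expected <- rep(-Inf, ncol(V))
    for (i in seq_len(nrow(V))) {
        p <- vapply(seq_len(ncol(V)), function(j)
            route_p(V[-i, j][case[-i]], V[-i, j][!case[-i]]), numeric(1))
        expected <- pmax(expected, p.adjust(p, "BH"))
    }
    got <- looFdr(co, cfg)
    expect_equal(unname(got), expected, tolerance = 1e-12)
})

test_that("the leave-one-out FDR controls nulls and detects a real shift", {
    flagged <- numeric(30)
    for (r in seq_len(30)) {
        co <- null_cohort(n_case = 15, n_control = 15, n_vars = 10,
                          seed = 300 + r)
        scr <- screenCohort(co, cfg)
        flagged[r] <- sum(scr$fdr < 0.10, na.rm = TRUE)
    }
    expect_lte(mean(flagged), 1)

    hits <- logical(25)
    for (r in seq_len(25)) {
        co <- planted_cohort(n_case = 50, n_control = 50, n_vars = 10,
                             shifts = 2, seed = 600 + r)
        scr <- screenCohort(co, cfg)
        hits[r] <- scr$fdr[scr$var_name == "var_001"] < 0.10
    }
    expect_gte(mean(hits), 0.95)
})

test_that("screenCohort composes per-variable pieces and sorts by AUROC", {
    co <- planted_cohort(n_case = 20, n_control = 20, n_vars = 1,
                         shifts = 1, seed = 13)
    scr <- screenCohort(co, cfg)
    V <- cohortValues(co)
    expect_equal(scr$auroc,
                 computeAuroc(V[isCase(co), 1], V[!isCase(co), 1])$auroc)

    co2 <- planted_cohort(n_case = 30, n_control = 30, n_vars = 6,
                          shifts = c(2, 1, 0.5), seed = 14)
    scr2 <- screenCohort(co2, cfg)
    expect_false(is.unsorted(rev(scr2$auroc)))
    expect_setequal(scr2$var_name, varNames(co2))
})

test_that("subjects missing a variable are dropped only for that variable", {
    co <- planted_cohort(n_case = 25, n_control = 25, n_vars = 4,
                         shifts = 1.5, seed = 17)
    V <- cohortValues(co)
    V[3, 2] <- NA  # a case subject loses variable 2
    co_miss <- raw_cohort(V, 25)
    co_drop <- raw_cohort(V[-3, ], 24)
    s_miss <- screenCohort(co_miss, cfg, loo_fdr = FALSE)
    s_drop <- screenCohort(co_drop, cfg, loo_fdr = FALSE)
    for (col in c("p_value", "auroc", "test_kind", "direction")) {
        expect_identical(s_miss[s_miss$var_name == "var_002", col],
                         s_drop[s_drop$var_name == "var_002", col])
    }
    expect_equal(s_miss$n_used_case[s_miss$var_name == "var_002"], 24)
    # the other variables keep all 50 subjects in the incomplete cohort
    expect_equal(s_miss$n_used_case[s_miss$var_name == "var_001"], 25)
})

test_that("constant variables are skipped with a log entry", {
    V <- cbind(matrix(rnorm(40), 20, 2), rep(5, 20))
    colnames(V) <- c("a", "b", "const")
    co <- raw_cohort(V, 10)
    expect_message(scr <- screenCohort(co, cfg, loo_fdr = FALSE), "const")
    expect_identical(attr(scr, "skipped"), "const")
    expect_equal(nrow(scr), 2)
})
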