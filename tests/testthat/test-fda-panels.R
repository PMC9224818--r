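test_that("one-variable FDA reduces to the variable itself", {
    set.seed(1)
    x <- matrix(c(rnorm(30, 1), rnorm(30)), ncol = 1,
                dimnames = list(NULL, "v"))
    y <- rep(c(TRUE, FALSE), each = 30)
    fit <- fitFda(x, y)
    expect_equal(abs(fit$w), 1)
    expect_equal(fit$fitted_auroc,
                 auroc_pairs_oracle(x[y, 1] * fit$w, x[!y, 1] * fit$w))
})

test_that("the closed form recovers the population discriminant", {
    set.seed(2)
    n <- 2000
    X <- rbind(matrix(rnorm(n * 3), n, 3),
               matrix(rnorm(n * 3), n, 3) +
                   matrix(c(2, 0, 0), n, 3, byrow = TRUE))
    colnames(X) <- paste0("v", 1:3)
    y <- rep(c(FALSE, TRUE), each = n)
    fit <- fitFda(X, y)
    cosine <- abs(sum(fit$w * c(1, 0, 0)))
    expect_gte(cosine, 0.99)
    expect_lt(abs(fit$fitted_auroc - pnorm(2 / sqrt(2))), 0.02)
})

test_that("collinear panels are handled by the ridge", {
    set.seed(3)
    x <- c(rnorm(40, 1.5), rnorm(40))
    y <- rep(c(TRUE, FALSE), each = 40)
    one <- fitFda(matrix(x, dimnames = list(NULL, "a")), y)
    dup <- fitFda(cbind(a = x, b = x), y)
    expect_lt(abs(dup$fitted_auroc - one$fitted_auroc), 1e-6)
})

test_that("the fitted direction maximizes the Rayleigh quotient", {
    set.seed(4)
    for (i in 1:10) {
        n <- 40
        X <- matrix(rnorm(2 * n * 2), 2 * n, 2) %*%
            matrix(c(1, 0.4, 0.4, 1), 2)
        X[seq_len(n), ] <- X[seq_len(n), ] +
            matrix(runif(2, -1.5, 1.5), n, 2, byrow = TRUE)
        y <- rep(c(TRUE, FALSE), each = n)
        w <- fitFda(X, y)$w
        Jw <- rayleigh_J(X, y, w)
        theta <- runif(1000, 0, 2 * pi)
        Jv <- vapply(seq_along(theta), function(k)
            rayleigh_J(X, y, c(cos(theta[k]), sin(theta[k]))), numeric(1))
        expect_gte(Jw, max(Jv) - 1e-8)
    }
})

test_that("AUROCs are invariant to positive rescaling of a variable", {
    co <- planted_cohort(n_case = 25, n_control = 20, n_vars = 3,
                         shifts = c(1, 0.8), seed = 5)
    e1 <- evaluatePanel(co, c("var_001", "var_002"), "fda")
    V <- cohortValues(co)
    V[, "var_002"] <- V[, "var_002"] * 1000
    e2 <- evaluatePanel(raw_cohort(V, 25), c("var_001", "var_002"), "fda")
    expect_lt(abs(e1$fitted_auroc - e2$fitted_auroc), 1e-10)
    expect_lt(abs(e1$cv_auroc - e2$cv_auroc), 1e-10)
})

test_that("LOOCV scores separate what is separable and not more", {
    X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
                dimnames = list(NULL, "v"))
    co <- raw_cohort(X[6:1, , drop = FALSE], 3)  # cases are 10,11,12
    ev <- evaluatePanel(co, "v", "fda")
    expect_equal(ev$cv_auroc, 1.0)
    expect_equal(ev$sensitivity, 1.0)
    expect_equal(ev$specificity, 1.0)

    # two independent planted variables beat either alone (most seeds)
    wins <- logical(10)
    for (r in seq_len(10)) {
        co2 <- planted_cohort(n_case = 55, n_control = 44, n_vars = 2,
                              shifts = c(1.5, 1.5), seed = 40 + r)
        both <- evaluatePanel(co2, c("var_001", "var_002"), "fda")$cv_auroc
        single <- max(
            evaluatePanel(co2, "var_001", "fda")$cv_auroc,
            evaluatePanel(co2, "var_002", "fda")$cv_auroc)
        wins[r] <- both > single
    }
    expect_gte(mean(wins), 0.9)
})

test_that("operating point maximizes Youden's J against a sweep oracle", {
    op <- operatingPoint(c(2, 3, 4, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
    # brute-force sweep over all cuts
    sweep_oracle <- function(scores, y) {
        cuts <- c(sort(unique(scores)), max(scores) + 1)
        best <- -Inf; out <- NULL
        for (thr in cuts) {
            sens <- mean(scores[y] >= thr); spec <- mean(scores[!y] < thr)
            if (sens + spec - 1 > best + 1e-12) {
                best <- sens + spec - 1; out <- c(sens, spec)
            }
        }
        out
    }
    expect_equal(unname(op[c("sensitivity", "specificity")]),
                 sweep_oracle(c(2, 3, 4, 1, 2, 3),
                              rep(c(TRUE, FALSE), each = 3)))
    set.seed(6)
    for (i in 1:20) {
        s <- round(rnorm(30), 1)
        y <- rep(c(TRUE, FALSE), c(16, 14))
        got <- operatingPoint(s, y)
        ora <- sweep_oracle(s, y)
        expect_equal(got[["sensitivity"]] + got[["specificity"]],
                     ora[1] + ora[2])
    }
    perfect <- operatingPoint(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(unname(perfect[c("sensitivity", "specificity")]), c(1, 1))
})

test_that("exhaustive search counts panels exactly and ranks planted ones", {
    co <- planted_cohort(n_case = 30, n_control = 30, n_vars = 10,
                         shifts = c(1.5, 1.5), seed = 7)
    cand <- varNames(co)
    expect_equal(nEvaluated(exhaustiveSearch(co, cand, 2, count_only = TRUE)),
                 choose(10, 2))
    led <- exhaustiveSearch(co, cand, 2, K = 10)
    expect_equal(nEvaluated(led), 45)
    expect_equal(nrow(ledgerModels(led)), 10)
    expect_false(is.unsorted(rev(ledgerModels(led)$cv_auroc)))
    # the planted pair should sit near the top most of the time
    tops <- logical(10)
    for (r in seq_len(10)) {
        coi <- planted_cohort(n_case = 30, n_control = 30, n_vars = 10,
                              shifts = c(1.5, 1.5), seed = 100 + r)
        li <- exhaustiveSearch(coi, varNames(coi), 2, K = 45)
        tops[r] <- "var_001|var_002" %in% head(ledgerModels(li)$panel, 5)
    }
    expect_gte(mean(tops), 0.9)
})

test_that("greedy extension at full retention equals exhaustive search", {
    co <- planted_cohort(n_case = 24, n_control = 20, n_vars = 8,
                         shifts = c(1.2, 1), seed = 8)
    cand <- varNames(co)
    l3 <- exhaustiveSearch(co, cand, 3, K = choose(8, 3))
    greedy4 <- greedyExtend(l3, co, cand, K = choose(8, 4))
    exact4 <- exhaustiveSearch(co, cand, 4, K = choose(8, 4))
    expect_equal(nEvaluated(greedy4), choose(8, 4))
    gm <- ledgerModels(greedy4)
    em <- ledgerModels(exact4)
    expect_identical(gm$panel, em$panel)
    expect_equal(gm$cv_auroc, em$cv_auroc)
    expect_equal(gm$fitted_auroc, em$fitted_auroc)
})

test_that("search results are deterministic and ties break by panel key", {
    co <- planted_cohort(n_case = 15, n_control = 15, n_vars = 6,
                         shifts = 1, seed = 9)
    a <- ledgerModels(exhaustiveSearch(co, varNames(co), 2, K = 15))
    b <- ledgerModels(exhaustiveSearch(co, varNames(co), 2, K = 15))
    expect_identical(a, b)
})

test_that("marker prevalence tallies the retained panels", {
    co <- planted_cohort(n_case = 20, n_control = 20, n_vars = 6,
                         shifts = c(2, 1.5), seed = 10)
    led <- exhaustiveSearch(co, varNames(co), 2, K = 5)
    prev <- markerPrevalence(led)
    expect_true(all(prev >= 0 & prev <= 1))
    expect_equal(sum(prev * nrow(ledgerModels(led))) / nrow(ledgerModels(led)),
                 2)  # prevalences sum to the panel size
    expect_true("var_001" %in% names(prev))
})

test_that("variant searches honor exclusions and complete-case restriction", {
    spec <- cohortSpec(n_case = 30, n_control = 30, n_vars = 8,
                       planted = plantedEffects(1:3, c(2, 1.5, 1.2)),
                       blocks_case = NULL, blocks_control = NULL,
                       marginal_families = "normal", case_sd_ratio = NULL,
                       missing_vars = 4:5, missing_rate = 0.08,
                       max_missing_per_var = 3, seed = 11)
    co <- generateCohort(spec)
    cand <- varNames(co)
    out <- runVariants(co, cand, exclude = "var_001", sizes = 2:3, K = 20,
                       plan = imputationPlan(n_imputations = 2, seed = 1),
                       n_imputations_search = 2)
    expect_named(out, c("full", "excluded", "complete_case"))
    prev_full <- markerPrevalence(out$full$k2)
    prev_excl <- markerPrevalence(out$excluded$k2)
    expect_false("var_001" %in% names(prev_excl))
    expect_gt(prev_full[["var_001"]], 0)
    # complete-case candidates exclude the variables with holes
    cc <- out$complete_case$k2@info$candidates
    expect_false(any(c("var_004", "var_005") %in% cc))

    # on a cohort with no missing cells, full and complete-case agree
    co2 <- planted_cohort(n_case = 20, n_control = 20, n_vars = 5,
                          shifts = 1.5, seed = 12)
    out2 <- runVariants(co2, varNames(co2), sizes = 2, K = 10)
    expect_identical(ledgerModels(out2$full$k2),
                     ledgerModels(out2$complete_case$k2))
    expect_warning(runVariants(co2, varNames(co2), exclude = "nope",
                               sizes = 2, K = 5),
                   "exclusion variables")
})
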