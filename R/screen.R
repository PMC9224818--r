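#' Screening configuration
#'
#' Thresholds for the univariate screen: the significance levels used
#' inside the test-selection tree (normality, variance equality,
#' distribution equality) and the final significance gates (p-value and
#' leave-one-out FDR).
#'
#' @param normality_alpha per-group Shapiro-Wilk level for the
#'   parametric/nonparametric split.
#' @param variance_alpha F-test level for equal-variance vs Welch t-test.
#' @param distribution_alpha two-sample Kolmogorov-Smirnov level for the
#'   nonparametric branch (raw and mean-centered stages).
#' @param p_threshold,fdr_threshold significance gates: a variable is
#'   significant iff `p < p_threshold` and `fdr < fdr_threshold`.
#' @return a list of class `ScreenConfig`.
#' @export
screenConfig <- function(normality_alpha = 0.05, variance_alpha = 0.05,
                         distribution_alpha = 0.05,
                         p_threshold = 0.05, fdr_threshold = 0.10) {
    cfg <- list(normality_alpha = normality_alpha,
                variance_alpha = variance_alpha,
                distribution_alpha = distribution_alpha,
                p_threshold = p_threshold, fdr_threshold = fdr_threshold)
    if (any(unlist(cfg) <= 0 | unlist(cfg) >= 1))
        stop("all ScreenConfig values must lie in (0, 1)")
    structure(cfg, class = "ScreenConfig")
}

# ---- fast two-sample p-values (cross-checked against stats:: in tests) ----

.p_shapiro <- function(x) {
    # Shapiro-Wilk needs 3..5000 non-identical values
    if (length(x) > 5000L) x <- x[seq_len(5000L)]
    stats::shapiro.test(x)$p.value
}

.p_var_f <- function(a, b) {
    f <- stats::var(a) / stats::var(b)
    p <- stats::pf(f, length(a) - 1L, length(b) - 1L)
    2 * min(p, 1 - p)
}

.p_t2 <- function(a, b, equal_var) {
    na <- length(a); nb <- length(b)
    va <- stats::var(a); vb <- stats::var(b)
    if (equal_var) {
        sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
        se <- sqrt(sp2 * (1 / na + 1 / nb))
        df <- na + nb - 2
    } else {
        se <- sqrt(va / na + vb / nb)
        df <- (va / na + vb / nb)^2 /
            ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    if (se == 0) return(if (mean(a) == mean(b)) 1 else 0)
    2 * stats::pt(-abs((mean(a) - mean(b)) / se), df)
}

.p_mann_whitney <- function(a, b) {
    na <- length(a); nb <- length(b)
    pooled <- c(a, b)
    r <- rank(pooled)
    U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- anyDuplicated(pooled) > 0L
    if (!ties && max(na, nb) <= 20L) {
        # exact enumeration via the wilcoxon rank-sum distribution
        p <- if (U > na * nb / 2)
            stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)
        else stats::pwilcox(U, na, nb)
        return(min(1, 2 * p))
    }
    mu <- na * nb / 2
    tie_tab <- rle(sort(pooled))$lengths
    n <- na + nb
    sigma2 <- na * nb / 12 *
        ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)  # continuity correction
    2 * stats::pnorm(-z)
}

.p_ks <- function(a, b) {
    # two-sample KS with the asymptotic Kolmogorov p-value: sufficient
    # for routing and far cheaper than the exact distribution inside the
    # leave-one-out sweeps (agrees with ks.test(exact = FALSE))
    n1 <- length(a)
    n2 <- length(b)
    w <- c(a, b)
    ord <- order(w)
    steps <- cumsum(ifelse(ord <= n1, 1 / n1, -1 / n2))
    sorted <- w[ord]
    keep <- c(diff(sorted) != 0, TRUE)   # midrank handling of ties
    D <- max(abs(steps[keep]))
    t <- sqrt(n1 * n2 / (n1 + n2)) * D
    k <- seq_len(25L)
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Select the hypothesis test for one variable
#'
#' Routes a case/control sample pair through the test-selection tree:
#' if both groups pass Shapiro-Wilk normality, an F-test on the variances
#' chooses between the equal-variance t-test and Welch's test. Otherwise
#' a two-sample Kolmogorov-Smirnov test compares the raw samples: if it
#' does not reject, the groups are treated as sharing a nonparametric
#' distribution and Mann-Whitney is used; if it rejects, both samples are
#' centered at their means and KS is re-run — not rejected routes to
#' Mann-Whitney, rejected to Welch's test (the centered samples are used
#' only for routing, never for the final p-value).
#'
#' @param sample_a,sample_b numeric vectors (>= 3 non-missing values
#'   each).
#' @param cfg a [screenConfig()].
#' @return one of `"t_equal_var"`, `"welch"`, `"mann_whitney"`,
#'   `"mean_adjusted_ks_then_mw"`, `"mean_adjusted_ks_then_welch"`.
#' @export
selectTest <- function(sample_a, sample_b, cfg = screenConfig()) {
    sample_a <- sample_a[!is.na(sample_a)]
    sample_b <- sample_b[!is.na(sample_b)]
    if (length(sample_a) < 3L || length(sample_b) < 3L)
        stop(degenerate_error("fewer than 3 non-missing values in a group"))
    if (stats::sd(sample_a) == 0 || stats::sd(sample_b) == 0)
        stop(degenerate_error("constant sample within a group"))
    normal <- .p_shapiro(sample_a) > cfg$normality_alpha &&
        .p_shapiro(sample_b) > cfg$normality_alpha
    if (normal) {
        if (.p_var_f(sample_a, sample_b) > cfg$variance_alpha)
            return("t_equal_var")
        return("welch")
    }
    if (.p_ks(sample_a, sample_b) > cfg$distribution_alpha)
        return("mann_whitney")
    centered_p <- .p_ks(sample_a - mean(sample_a), sample_b - mean(sample_b))
    if (centered_p > cfg$distribution_alpha)
        "mean_adjusted_ks_then_mw"
    else
        "mean_adjusted_ks_then_welch"
}

#' Run the selected two-sample test
#'
#' Computes the two-sided p-value of the test chosen by [selectTest()].
#' The mean-adjusted variants apply Mann-Whitney or Welch to the
#' *original* (uncentered) samples; centering happens only during
#' selection.
#'
#' @inheritParams selectTest
#' @param test_kind value returned by [selectTest()].
#' @return two-sided p-value.
#' @export
runTest <- function(sample_a, sample_b, test_kind) {
    sample_a <- sample_a[!is.na(sample_a)]
    sample_b <- sample_b[!is.na(sample_b)]
    switch(test_kind,
        t_equal_var = .p_t2(sample_a, sample_b, equal_var = TRUE),
        welch = ,
        mean_adjusted_ks_then_welch = .p_t2(sample_a, sample_b, equal_var = FALSE),
        mann_whitney = ,
        mean_adjusted_ks_then_mw = .p_mann_whitney(sample_a, sample_b),
        stop(sprintf("unknown test kind '%s'", test_kind)))
}

#' Per-variable AUROC with direction
#'
#' Treats the measurements as classification scores and computes the
#' rank-method AUROC with midrank tie handling: the raw statistic is
#' `A = P(case > control) + 0.5 P(tie)`. The reported AUROC is folded to
#' `max(A, 1 - A)` with a separate direction flag (`"case_higher"` iff
#' `A >= 0.5`; ties at exactly 0.5 break to `"case_higher"`).
#'
#' @param case_values,control_values numeric vectors (>= 1 value each,
#'   missing values dropped).
#' @return list with `auroc`, `direction` and the raw statistic `raw`.
#' @export
computeAuroc <- function(case_values, control_values) {
    case_values <- case_values[!is.na(case_values)]
    control_values <- control_values[!is.na(control_values)]
    a <- auroc_raw(case_values, control_values)
    list(auroc = max(a, 1 - a),
         direction = if (a >= 0.5) "case_higher" else "case_lower",
         raw = a)
}

# p-values (and routing) for every variable on one subject subset.
# Returns data.frame(p, kind); NA rows are degenerate variables (logged).
.screen_pvalues <- function(V, is_case, cfg) {
    p <- numeric(ncol(V))
    kind <- character(ncol(V))
    for (j in seq_len(ncol(V))) {
        x <- V[, j]
        a <- x[is_case & !is.na(x)]
        b <- x[!is_case & !is.na(x)]
        k <- tryCatch(selectTest(a, b, cfg),
                      metabopanels_degenerate = function(e) NA_character_)
        if (is.na(k)) {
            p[j] <- NA_real_; kind[j] <- NA_character_
        } else {
            p[j] <- runTest(a, b, k); kind[j] <- k
        }
    }
    data.frame(p = p, kind = kind, stringsAsFactors = FALSE)
}

#' Leave-one-out false-discovery rates
#'
#' The stability-oriented FDR of the screen: for each subject in turn,
#' that subject is removed, every variable's p-value is recomputed with
#' the full test-selection routing on the reduced cohort, and
#' Benjamini-Hochberg is applied across variables. A variable's FDR is
#' the worst (maximum) of its BH q-values over all leave-one-out
#' replicates, a conservative estimate of how stable each discovery is
#' to any single subject.
#'
#' @param cohort a [MetaboCohort-class].
#' @param cfg a [screenConfig()].
#' @return named numeric vector of FDR values, one per variable
#'   (`NA` for variables degenerate in some replicate).
#' @export
looFdr <- function(cohort, cfg = screenConfig()) {
    V <- cohortValues(cohort)
    case <- isCase(cohort)
    n <- nrow(V)
    if (min(sum(case), sum(!case)) < 4L)
        stop("leave-one-out FDR needs at least 4 subjects per group")
    qmax <- rep(-Inf, ncol(V))
    for (i in seq_len(n)) {
        pv <- .screen_pvalues(V[-i, , drop = FALSE], case[-i], cfg)$p
        q <- bh_adjust(pv)
        qmax <- pmax(qmax, q)   # NA propagates: unstable variable
    }
    qmax[!is.finite(qmax) & !is.na(qmax)] <- NA_real_
    names(qmax) <- colnames(V)
    qmax
}

#' Univariate screen of a cohort
#'
#' Runs the full univariate stage: per-variable test selection and
#' two-sided p-value (subjects missing a variable are dropped for that
#' variable only), rank AUROC with direction, and (optionally) the
#' leave-one-out FDR. A variable is flagged significant when
#' `p < p_threshold` and `fdr < fdr_threshold`.
#'
#' @param cohort a [MetaboCohort-class].
#' @param cfg a [screenConfig()].
#' @param loo_fdr compute the leave-one-out FDR (the default); when
#'   `FALSE` the `fdr` column falls back to plain Benjamini-Hochberg on
#'   the full-cohort p-values.
#' @return `data.frame`, one row per variable, sorted by descending
#'   AUROC, with columns `var_name`, `source`, `direction`, `p_value`,
#'   `test_kind`, `auroc`, `fdr`, `n_used_case`, `n_used_control`,
#'   `significant`. Degenerate variables (constant / too few values) are
#'   dropped, with their names in `attr(, "skipped")`.
#' @export
screenCohort <- function(cohort, cfg = screenConfig(), loo_fdr = TRUE) {
    stopifnot(is(cohort, "MetaboCohort"))
    V <- cohortValues(cohort)
    case <- isCase(cohort)
    pv <- .screen_pvalues(V, case, cfg)
    fdr <- if (loo_fdr) looFdr(cohort, cfg) else bh_adjust(pv$p)
    src <- rowData(cohort)$source
    if (is.null(src)) src <- rep(NA_character_, ncol(V))
    res <- data.frame(var_name = colnames(V), source = src,
                      direction = NA_character_, p_value = pv$p,
                      test_kind = pv$kind, auroc = NA_real_,
                      fdr = as.numeric(fdr),
                      n_used_case = NA_integer_, n_used_control = NA_integer_,
                      stringsAsFactors = FALSE)
    for (j in seq_len(ncol(V))) {
        x <- V[, j]
        a <- x[case & !is.na(x)]
        b <- x[!case & !is.na(x)]
        res$n_used_case[j] <- length(a)
        res$n_used_control[j] <- length(b)
        if (length(a) && length(b)) {
            au <- computeAuroc(a, b)
            res$auroc[j] <- au$auroc
            res$direction[j] <- au$direction
        }
    }
    skipped <- res$var_name[is.na(res$test_kind)]
    if (length(skipped))
        message(sprintf("screenCohort: skipped %d degenerate variable(s): %s",
                        length(skipped), paste(skipped, collapse = ", ")))
    res <- res[!is.na(res$test_kind), , drop = FALSE]
    res$significant <- !is.na(res$p_value) & !is.na(res$fdr) &
        res$p_value < cfg$p_threshold & res$fdr < cfg$fdr_threshold
    res <- res[order(-res$auroc, res$var_name), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "skipped") <- skipped
    attr(res, "config") <- cfg
    res
}
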