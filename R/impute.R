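#' Imputation plan
#'
#' Settings for density-based multiple imputation: number of completed
#' datasets, kernel bandwidth rule and the base seed. Imputation is
#' always per group: a missing cell is drawn from the density fitted to
#' the observed values of that variable *within the subject's group*.
#'
#' @param n_imputations number of completed datasets (>= 1).
#' @param bandwidth_rule `"silverman"` ([stats::bw.nrd0]) or `"scott"`
#'   ([stats::bw.nrd]).
#' @param seed base seed; imputation `m` uses `seed + m`, so any single
#'   replicate is reproducible in isolation.
#' @return a list of class `ImputationPlan`.
#' @export
imputationPlan <- function(n_imputations = 100L,
                           bandwidth_rule = c("silverman", "scott"),
                           seed = 1L) {
    n_imputations <- as.integer(n_imputations)
    if (n_imputations < 1L) stop("n_imputations must be >= 1")
    structure(list(n_imputations = n_imputations,
                   bandwidth_rule = match.arg(bandwidth_rule),
                   seed = as.integer(seed)),
              class = "ImputationPlan")
}

#' Fit a one-dimensional density sampler
#'
#' Gaussian-kernel density estimate of the observed values, returned as
#' a sampling function: a draw is a resampled observation plus kernel
#' noise. When all observed values are strictly positive, draws are
#' clipped to the observed range so imputed concentrations can never go
#' negative. With fewer than 5 observations, or a degenerate (constant)
#' sample, the sampler falls back to plain empirical resampling with a
#' warning.
#'
#' @param observed_values numeric vector (missing values dropped).
#' @param bandwidth_rule `"silverman"` or `"scott"`.
#' @return `function(n)` producing `n` independent draws.
#' @export
fitDensitySampler <- function(observed_values,
                              bandwidth_rule = c("silverman", "scott")) {
    bandwidth_rule <- match.arg(bandwidth_rule)
    obs <- observed_values[!is.na(observed_values)]
    if (length(obs) == 0L)
        stop("no observed values to fit a density to")
    if (length(obs) < 5L || stats::sd(obs) == 0) {
        warning("too few (or constant) observed values; falling back to empirical resampling")
        return(function(n) obs[sample.int(length(obs), n, replace = TRUE)])
    }
    bw <- switch(bandwidth_rule, silverman = stats::bw.nrd0(obs),
                 scott = stats::bw.nrd(obs))
    clip <- all(obs > 0)
    lo <- min(obs); hi <- max(obs)
    function(n) {
        x <- obs[sample.int(length(obs), n, replace = TRUE)] +
            stats::rnorm(n, 0, bw)
        if (clip) x <- pmin(pmax(x, lo), hi)
        x
    }
}

#' Multiple imputation of a cohort
#'
#' Produces `plan$n_imputations` completed cohorts. Each missing cell is
#' drawn from the kernel density fitted to the observed values of that
#' variable in the subject's own group; observed cells are never
#' touched, and a cohort without missing cells is returned unchanged.
#' Deterministic under the plan's seed ladder.
#'
#' @param cohort a [MetaboCohort-class].
#' @param plan an [imputationPlan()].
#' @return list of [MetaboCohort-class] objects, each carrying
#'   `metadata()$imputation_index` and `metadata()$imputed_mask`
#'   (the provenance mask of filled cells).
#' @export
imputeCohort <- function(cohort, plan = imputationPlan()) {
    stopifnot(is(cohort, "MetaboCohort"))
    V <- cohortValues(cohort)
    case <- isCase(cohort)
    mask <- is.na(V)
    miss_vars <- which(colSums(mask) > 0L)
    for (j in miss_vars) {
        for (g in list(case, !case)) {
            if (all(is.na(V[g, j])))
                stop(sprintf("variable '%s' is fully missing in one group",
                             colnames(V)[j]))
        }
    }
    samplers <- list()
    for (j in miss_vars) {
        samplers[[as.character(j)]] <- list(
            case = fitDensitySampler(V[case, j], plan$bandwidth_rule),
            control = fitDensitySampler(V[!case, j], plan$bandwidth_rule))
    }
    out <- vector("list", plan$n_imputations)
    for (m in seq_len(plan$n_imputations)) {
        Vm <- V
        with_seed(plan$seed + m, {
            for (j in miss_vars) {
                for (grp in c("case", "control")) {
                    g <- if (grp == "case") case else !case
                    holes <- which(g & mask[, j])
                    if (length(holes))
                        Vm[holes, j] <- samplers[[as.character(j)]][[grp]](length(holes))
                }
            }
        })
        co <- MetaboCohort(Vm, group = groupLabels(cohort),
                           case_label = metadata(cohort)$case_label,
                           var_meta = as.data.frame(rowData(cohort)))
        metadata(co)$imputation_index <- m
        metadata(co)$imputed_mask <- mask
        out[[m]] <- co
    }
    out
}

#' Pool a statistic across imputations
#'
#' Plain averaging across imputation replicates (as used for pooling
#' classifier AUROCs), with the across-imputation standard deviation as
#' the spread (0 for a single replicate).
#'
#' @param per_imputation_statistics numeric vector (>= 1 value).
#' @return named numeric: `mean`, `spread`.
#' @export
poolStatistics <- function(per_imputation_statistics) {
    x <- per_imputation_statistics
    if (!length(x)) stop("need at least one statistic to pool")
    c(mean = mean(x),
      spread = if (length(x) > 1L) stats::sd(x) else 0)
}
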