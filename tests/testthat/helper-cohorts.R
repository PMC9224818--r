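# Small cohort builders shared across tests. Everything is generated in
# code under fixed seeds; no fixture files.

# A cohort with independent standard-normal variables and no group effect.
null_cohort <- function(n_case = 20, n_control = 20, n_vars = 5, seed = 1) {
    generateCohort(cohortSpec(
        n_case = n_case, n_control = n_control, n_vars = n_vars,
        planted = NULL, blocks_case = NULL, blocks_control = NULL,
        marginal_families = "normal", case_sd_ratio = NULL,
        missing_vars = NULL, missing_rate = 0, seed = seed))
}

# A cohort with planted shifts on the first variables, normal marginals.
planted_cohort <- function(n_case = 55, n_control = 44, n_vars = 10,
                           shifts = 1.5, n_planted = length(shifts),
                           seed = 1, direction = "case_higher") {
    generateCohort(cohortSpec(
        n_case = n_case, n_control = n_control, n_vars = n_vars,
        planted = plantedEffects(seq_len(n_planted),
                                 standardized_shift = shifts,
                                 direction = direction),
        blocks_case = NULL, blocks_control = NULL,
        marginal_families = "normal", case_sd_ratio = NULL,
        missing_vars = NULL, missing_rate = 0, seed = seed))
}

# Build a MetaboCohort directly from a matrix (case labels first).
raw_cohort <- function(values, n_case, ...) {
    MetaboCohort(values,
                 group = rep(c("case", "control"),
                             c(n_case, nrow(values) - n_case)),
                 case_label = "case", ...)
}

# Brute-force all-pairs AUROC oracle (independent of the rank method).
auroc_pairs_oracle <- function(case, control) {
    wins <- outer(case, control, ">")
    ties <- outer(case, control, "==")
    (sum(wins) + 0.5 * sum(ties)) / (length(case) * length(control))
}

# Rayleigh quotient J(w) for a two-class problem (test-side oracle).
rayleigh_J <- function(X, is_case, w) {
    mu1 <- colMeans(X[is_case, , drop = FALSE])
    mu0 <- colMeans(X[!is_case, , drop = FALSE])
    mu <- colMeans(X)
    n1 <- sum(is_case); n0 <- sum(!is_case)
    SB <- n1 * tcrossprod(mu1 - mu) + n0 * tcrossprod(mu0 - mu)
    SW <- crossprod(sweep(X[is_case, , drop = FALSE], 2, mu1)) +
        crossprod(sweep(X[!is_case, , drop = FALSE], 2, mu0))
    as.numeric((t(w) %*% SB %*% w) / (t(w) %*% SW %*% w))
}
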