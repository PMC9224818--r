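#' Convert between standardized shift and AUROC
#'
#' For two unit-variance normal populations whose means differ by `d`,
#' the AUROC of the variable as a classifier is `pnorm(d / sqrt(2))`.
#' These helpers convert in both directions and are used to plant effects
#' with target per-variable AUROCs.
#'
#' @param auroc,shift numeric vectors.
#' @return numeric vector.
#' @export
aurocToShift <- function(auroc) {
    stopifnot(all(auroc >= 0.5 & auroc < 1))
    sqrt(2) * stats::qnorm(auroc)
}

#' @rdname aurocToShift
#' @export
shiftToAuroc <- function(shift) stats::pnorm(shift / sqrt(2))

#' Planted group effects
#'
#' Builds the `planted` table of a [CohortSpec-class]: which variables
#' carry a true group difference, how large (Cohen-d scale) and in which
#' direction. Specify either `standardized_shift` directly or a target
#' per-variable `auroc` (converted via [aurocToShift()]).
#'
#' @param var_index integer indices of the affected variables.
#' @param standardized_shift positive shifts on the pooled-SD scale.
#' @param auroc alternative to `standardized_shift`.
#' @param direction `"case_higher"` or `"case_lower"`, recycled.
#' @return `data.frame` with columns `var_index`, `standardized_shift`,
#'   `direction`.
#' @export
plantedEffects <- function(var_index, standardized_shift = NULL,
                           auroc = NULL, direction = "case_higher") {
    var_index <- as.integer(var_index)
    if (length(var_index) == 0L)
        return(data.frame(var_index = integer(), standardized_shift = numeric(),
                          direction = character(), stringsAsFactors = FALSE))
    if (is.null(standardized_shift)) {
        if (is.null(auroc))
            stop("provide standardized_shift or auroc")
        standardized_shift <- aurocToShift(auroc)
    }
    data.frame(var_index = var_index,
               standardized_shift = rep_len(standardized_shift, length(var_index)),
               direction = rep_len(direction, length(var_index)),
               stringsAsFactors = FALSE)
}

.study_planted <- function(n_planted = 46L) {
    # Per-variable AUROCs spanning 0.9 down to 0.6. The strongest
    # markers (which the default blocks make mutually correlated) share
    # a direction -- a correlated metabolite cluster moves together --
    # while the weaker, unstructured markers mix directions.
    auroc <- seq(0.90, 0.60, length.out = n_planted)
    direction <- rep_len(c("case_lower", "case_higher"), n_planted)
    direction[intersect(1:12, seq_len(n_planted))] <- "case_lower"
    direction[intersect(13:20, seq_len(n_planted))] <- "case_higher"
    direction[intersect(21:26, seq_len(n_planted))] <- "case_lower"
    plantedEffects(seq_len(n_planted), auroc = auroc,
                   direction = direction)
}

.study_blocks <- function(side) {
    # The strong markers form sizeable correlated clusters in BOTH
    # groups (each top marker correlates with many others), while the
    # control group's clusters are larger and it carries an extra one,
    # making the control network clearly denser.
    if (side == "control")
        list(list(vars = 1:12, rho = 0.55),
             list(vars = 13:20, rho = 0.50),
             list(vars = 21:26, rho = 0.45))
    else
        list(list(vars = 1:8, rho = 0.55),
             list(vars = 13:17, rho = 0.50))
}

.study_families <- function(n_vars) {
    fam <- rep("normal", n_vars)
    fam[seq_len(n_vars) %% 5L == 0L] <- "lognormal"
    fam[seq_len(n_vars) %% 7L == 0L] <- "heavy_tail"
    fam
}

.study_sd_ratio <- function(n_vars, planted) {
    r <- rep(1, n_vars)
    if (nrow(planted)) {
        idx <- planted$var_index
        r[idx[seq_along(idx) %% 3L == 0L]] <- 1.75
    }
    r
}

#' Build a cohort specification
#'
#' Returns a [CohortSpec-class]. The defaults encode the study conditions
#' the package's simulations assume throughout: 55 case and 44 control
#' subjects over 155 variables; 46 planted effects with per-variable
#' AUROCs spanning 0.6-0.9 in mixed directions; correlation blocks denser
#' in the control group than in the case group; a mix of normal,
#' lognormal and heavy-tailed marginals with some group-heteroscedastic
#' variables (so every branch of the test-selection tree occurs); and
#' MCAR missing cells on 20 of the planted variables, capped at 4 missing
#' subjects per variable.
#'
#' Pass `planted = NULL`, `blocks_case = NULL` etc. to switch a component
#' off (e.g. a fully null cohort), or explicit values to override.
#'
#' @param n_case,n_control,n_vars cohort dimensions.
#' @param planted `"study"`, `NULL`, or a table from [plantedEffects()].
#' @param blocks_case,blocks_control `"study"`, `NULL`, or a list of
#'   `list(vars =, rho =)` blocks.
#' @param marginal_families `"study"`, or a character vector/scalar in
#'   `"normal"`, `"lognormal"`, `"heavy_tail"`.
#' @param case_sd_ratio `"study"`, `NULL` (all 1), or a numeric
#'   vector/scalar of case-to-control latent SD ratios.
#' @param missing_vars `"study"` (20 planted variables), `NULL`, or
#'   integer indices.
#' @param missing_rate per-cell MCAR probability for those variables.
#' @param max_missing_per_var cap on missing subjects per variable.
#' @param seed integer; generation is deterministic given the spec.
#' @return a [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(seed = 7)
#' co <- generateCohort(spec)
#' co
#' @export
cohortSpec <- function(n_case = 55L, n_control = 44L, n_vars = 155L,
                       planted = "study",
                       blocks_case = "study", blocks_control = "study",
                       marginal_families = "study",
                       case_sd_ratio = "study",
                       missing_vars = "study",
                       missing_rate = 0.02,
                       max_missing_per_var = 4L,
                       seed = 1L) {
    n_vars <- as.integer(n_vars)
    if (identical(planted, "study"))
        planted <- .study_planted(min(46L, n_vars))
    if (is.null(planted))
        planted <- plantedEffects(integer())
    if (identical(blocks_case, "study"))
        blocks_case <- Filter(function(b) max(b$vars) <= n_vars, .study_blocks("case"))
    if (identical(blocks_control, "study"))
        blocks_control <- Filter(function(b) max(b$vars) <= n_vars, .study_blocks("control"))
    if (identical(marginal_families, "study"))
        marginal_families <- .study_families(n_vars)
    marginal_families <- rep_len(marginal_families, n_vars)
    if (identical(case_sd_ratio, "study"))
        case_sd_ratio <- .study_sd_ratio(n_vars, planted)
    if (is.null(case_sd_ratio)) case_sd_ratio <- 1
    case_sd_ratio <- rep_len(as.numeric(case_sd_ratio), n_vars)
    if (identical(missing_vars, "study"))
        missing_vars <- planted$var_index[seq_len(min(20L, nrow(planted)))]
    missing_vars <- as.integer(missing_vars %||% integer())
    new("CohortSpec",
        n_case = as.integer(n_case), n_control = as.integer(n_control),
        n_vars = n_vars, planted = planted,
        blocks_case = blocks_case %||% list(),
        blocks_control = blocks_control %||% list(),
        marginal_families = marginal_families,
        case_sd_ratio = case_sd_ratio,
        missing_vars = missing_vars,
        missing_rate = missing_rate,
        max_missing_per_var = as.integer(max_missing_per_var),
        seed = as.integer(seed))
}

# Latent Gaussian matrix for one group with the block structure applied.
.latent_group <- function(n, n_vars, blocks) {
    Z <- matrix(stats::rnorm(n * n_vars), n, n_vars)
    for (b in blocks) {
        f <- stats::rnorm(n)
        for (j in b$vars)
            Z[, j] <- sqrt(abs(b$rho)) * sign(b$rho) * f +
                sqrt(1 - abs(b$rho)) * stats::rnorm(n)
    }
    Z
}

#' Generate a synthetic cohort
#'
#' Draws a [MetaboCohort-class] from a [CohortSpec-class]. Variables are
#' built on a latent Gaussian scale (where correlation blocks and planted
#' shifts are exact) and then pushed through the per-variable marginal
#' transform: `normal` maps to `100 + 15 z`, `lognormal` to `exp(z)`, and
#' `heavy_tail` to the t3 quantile of `pnorm(z)`. All transforms are
#' monotone, so a planted effect's AUROC is invariant to the marginal
#' family. Planted shifts are scaled so that for normal
#' marginals the difference of group means over the pooled SD equals the
#' requested standardized shift in expectation; for transformed marginals
#' the shift lives on the latent scale. MCAR missingness is applied last,
#' capped per variable.
#'
#' Identical specs (including seed) produce bit-identical cohorts.
#'
#' @param spec a [CohortSpec-class].
#' @return a [MetaboCohort-class] with planted-effect truth in `rowData`
#'   and the spec stored in `metadata`.
#' @export
generateCohort <- function(spec) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    n1 <- spec@n_case; n0 <- spec@n_control; p <- spec@n_vars
    with_seed(spec@seed, {
        Zc <- .latent_group(n1, p, spec@blocks_case)
        Zt <- .latent_group(n0, p, spec@blocks_control)
        # group-heteroscedastic variables (latent scale)
        Zc <- Zc * matrix(spec@case_sd_ratio, n1, p, byrow = TRUE)
        # planted shifts, scaled so the pooled-SD shift equals the request
        if (nrow(spec@planted)) {
            for (i in seq_len(nrow(spec@planted))) {
                j <- spec@planted$var_index[i]
                r <- spec@case_sd_ratio[j]
                delta <- spec@planted$standardized_shift[i] * sqrt((1 + r^2) / 2)
                sgn <- if (spec@planted$direction[i] == "case_higher") 1 else -1
                Zc[, j] <- Zc[, j] + sgn * delta
            }
        }
        Z <- rbind(Zc, Zt)
        X <- Z
        for (j in seq_len(p)) {
            X[, j] <- switch(spec@marginal_families[j],
                normal = 100 + 15 * Z[, j],
                lognormal = exp(Z[, j]),
                # monotone Gaussian-copula map to a t3 marginal, so planted
                # rank structure (AUROC) survives the transform
                heavy_tail = stats::qt(stats::pnorm(Z[, j]), df = 3))
        }
        # MCAR missingness with a per-variable cap
        if (length(spec@missing_vars) && spec@missing_rate > 0) {
            n <- n1 + n0
            for (j in spec@missing_vars) {
                k <- min(stats::rbinom(1L, n, spec@missing_rate),
                         spec@max_missing_per_var)
                if (k > 0L)
                    X[sample.int(n, k), j] <- NA_real_
            }
        }
        colnames(X) <- sprintf("var_%03d", seq_len(p))
        rownames(X) <- sprintf("S%03d", seq_len(n1 + n0))
        planted_flag <- logical(p)
        planted_shift <- rep(NA_real_, p)
        planted_dir <- rep(NA_character_, p)
        if (nrow(spec@planted)) {
            planted_flag[spec@planted$var_index] <- TRUE
            planted_shift[spec@planted$var_index] <- spec@planted$standardized_shift
            planted_dir[spec@planted$var_index] <- spec@planted$direction
        }
        meta <- data.frame(
            source = rep_len(c("plasma", "RBC", "urine", "whole_blood",
                               "platelets"), p),
            family = spec@marginal_families,
            planted = planted_flag,
            planted_shift = planted_shift,
            planted_direction = planted_dir,
            stringsAsFactors = FALSE)
        co <- MetaboCohort(X, group = rep(c("case", "control"), c(n1, n0)),
                           case_label = "case", var_meta = meta)
        metadata(co)$spec <- spec
        co
    })
}
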