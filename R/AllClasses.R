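#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Cohort specification for the synthetic generator
#'
#' A `CohortSpec` fully describes a synthetic case-control cohort:
#' group sizes, number of variables, planted standardized group shifts,
#' per-group correlation-block structure, marginal families, per-variable
#' case/control spread ratios and an MCAR missingness plan. Together with
#' the seed it determines the generated data exactly.
#'
#' @slot n_case,n_control number of case / control subjects.
#' @slot n_vars number of measured variables.
#' @slot planted `data.frame` with columns `var_index`, `standardized_shift`
#'   (Cohen-d scale, positive) and `direction` (`"case_higher"` /
#'   `"case_lower"`).
#' @slot blocks_case,blocks_control list of correlation blocks, each a
#'   `list(vars = <integer indices>, rho = <within-block correlation>)`,
#'   applied per group on the latent Gaussian scale.
#' @slot marginal_families character vector (length `n_vars`) with values
#'   in `"normal"`, `"lognormal"`, `"heavy_tail"`.
#' @slot case_sd_ratio per-variable ratio of case to control spread on the
#'   latent scale (1 = homoscedastic).
#' @slot missing_vars indices of variables that receive MCAR missing cells.
#' @slot missing_rate per-cell MCAR rate for those variables.
#' @slot max_missing_per_var hard cap on missing subjects per variable.
#' @slot seed integer seed; generation is a pure function of the spec.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec", representation(
    n_case = "integer",
    n_control = "integer",
    n_vars = "integer",
    planted = "data.frame",
    blocks_case = "list",
    blocks_control = "list",
    marginal_families = "character",
    case_sd_ratio = "numeric",
    missing_vars = "integer",
    missing_rate = "numeric",
    max_missing_per_var = "integer",
    seed = "integer"
))

setValidity("CohortSpec", function(object) {
    msg <- character()
    n <- object@n_case + object@n_control
    if (n < 4L)
        msg <- c(msg, "n_case + n_control must be >= 4")
    if (object@n_vars < 1L)
        msg <- c(msg, "n_vars must be >= 1")
    pl <- object@planted
    if (nrow(pl)) {
        if (!all(c("var_index", "standardized_shift", "direction") %in% names(pl)))
            msg <- c(msg, "planted must have var_index, standardized_shift, direction")
        else {
            if (anyDuplicated(pl$var_index))
                msg <- c(msg, "planted: var_index values must be distinct")
            if (any(pl$var_index < 1L | pl$var_index > object@n_vars))
                msg <- c(msg, "planted: var_index out of range")
            if (any(pl$standardized_shift <= 0))
                msg <- c(msg, "planted: standardized_shift must be > 0")
            if (!all(pl$direction %in% c("case_higher", "case_lower")))
                msg <- c(msg, "planted: direction must be case_higher/case_lower")
        }
    }
    for (side in c("blocks_case", "blocks_control")) {
        for (b in slot(object, side)) {
            if (!is.list(b) || is.null(b$vars) || is.null(b$rho)) {
                msg <- c(msg, sprintf("%s: each block needs $vars and $rho", side))
                next
            }
            if (any(b$vars < 1L | b$vars > object@n_vars))
                msg <- c(msg, sprintf("%s: block indices out of range", side))
            if (abs(b$rho) >= 1)
                msg <- c(msg, sprintf("%s: |rho| must be < 1", side))
        }
    }
    if (length(object@marginal_families) != object@n_vars)
        msg <- c(msg, "marginal_families must have length n_vars")
    if (!all(object@marginal_families %in% c("normal", "lognormal", "heavy_tail")))
        msg <- c(msg, "marginal_families values must be normal/lognormal/heavy_tail")
    if (length(object@case_sd_ratio) != object@n_vars ||
        any(object@case_sd_ratio <= 0))
        msg <- c(msg, "case_sd_ratio must be positive, length n_vars")
    if (length(object@missing_vars) &&
        any(object@missing_vars < 1L | object@missing_vars > object@n_vars))
        msg <- c(msg, "missing_vars out of range")
    if (object@missing_rate < 0 || object@missing_rate >= 1)
        msg <- c(msg, "missing_rate must be in [0, 1)")
    if (object@max_missing_per_var >= min(object@n_case, object@n_control))
        msg <- c(msg, "max_missing_per_var must be < min(n_case, n_control)")
    if (length(msg)) msg else TRUE
})

#' Subject-by-variable cohort container
#'
#' `MetaboCohort` extends [SummarizedExperiment::SummarizedExperiment] with
#' variables as rows and subjects as columns. The single assay `"exprs"`
#' holds the measurements with `NA` marking missing cells; `colData`
#' carries the two-level group label; `rowData` may carry a specimen
#' source tag and, for synthetic cohorts, the planted-effect truth.
#'
#' Use [cohortValues()] to obtain the conventional subjects-by-variables
#' matrix, and [groupLabels()] / [isCase()] for the group assignment.
#'
#' @export
setClass("MetaboCohort", contains = "SummarizedExperiment")

setValidity("MetaboCohort", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- colData(object)
    if (!"group" %in% names(cd))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        g <- cd$group
        if (anyNA(g))
            msg <- c(msg, "group labels must not be missing")
        else if (length(unique(as.character(g))) != 2L)
            msg <- c(msg, "exactly two group labels must be present")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "variable names must be present and unique")
    cl <- metadata(object)$case_label
    if (is.null(cl) || !cl %in% as.character(colData(object)$group))
        msg <- c(msg, "metadata case_label must name one of the group labels")
    if (length(msg)) msg else TRUE
})

#' Thresholded per-group correlation network
#'
#' Holds the edges that pass the three gates (|r| > r_min, p < p_max,
#' leave-one-out FDR < fdr_max) over a node universe of screened
#' variables, for one group.
#'
#' @slot group `"case"`, `"control"` or `"combined"`.
#' @slot nodes variable identifiers forming the node universe.
#' @slot edges `data.frame` with columns `var_a`, `var_b`, `r`, `p_value`,
#'   `fdr`, `n_pairs` (one row per unordered pair passing the gates).
#' @slot gates named numeric: `r_min`, `p_max`, `fdr_max`.
#' @export
setClass("CorrelationNetwork", representation(
    group = "character",
    nodes = "character",
    edges = "data.frame",
    gates = "numeric"
))

setValidity("CorrelationNetwork", function(object) {
    msg <- character()
    need <- c("var_a", "var_b", "r", "p_value", "fdr", "n_pairs")
    if (!all(need %in% names(object@edges)))
        msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
    if (!all(c("r_min", "p_max", "fdr_max") %in% names(object@gates)))
        msg <- c(msg, "gates must name r_min, p_max, fdr_max")
    if (nrow(object@edges)) {
        e <- object@edges
        if (any(abs(e$r) > 1 + 1e-12)) msg <- c(msg, "|r| must be <= 1")
        if (any(e$n_pairs < 3)) msg <- c(msg, "edges require n_pairs >= 3")
        key <- paste(pmin(e$var_a, e$var_b), pmax(e$var_a, e$var_b))
        if (anyDuplicated(key)) msg <- c(msg, "duplicate unordered pairs in edges")
    }
    if (length(msg)) msg else TRUE
})

#' Ranked collection of evaluated biomarker panels
#'
#' A `SearchLedger` is the result of an exhaustive or greedy panel search
#' at one panel size: the top-K panels ranked by cross-validated
#' performance, together with the total number of panels evaluated (the
#' combinatorial counter) and, for SVM searches, the training-accuracy
#' gate bookkeeping.
#'
#' @slot method `"fda"` or `"svm"`.
#' @slot panelSize number of variables per panel.
#' @slot K retention cap.
#' @slot models `data.frame`, one row per retained panel, sorted by the
#'   ranking key; column `panel` is a `"|"`-joined member key.
#' @slot nEvaluated exact count of panels evaluated (or enumerated in
#'   counting mode).
#' @slot info free-form list (candidate set, gate counts, imputation use).
#' @export
setClass("SearchLedger", representation(
    method = "character",
    panelSize = "integer",
    K = "integer",
    models = "data.frame",
    nEvaluated = "numeric",
    info = "list"
))

setValidity("SearchLedger", function(object) {
    msg <- character()
    if (!object@method %in% c("fda", "svm"))
        msg <- c(msg, "method must be 'fda' or 'svm'")
    if (nrow(object@models) > object@K)
        msg <- c(msg, "more retained models than K")
    if (nrow(object@models) && is.unsorted(rev(object@models$cv_auroc))
        && object@method == "fda")
        msg <- c(msg, "FDA models must be sorted by descending cv_auroc")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MetaboCohort", function(object) {
    g <- as.character(colData(object)$group)
    cl <- metadata(object)$case_label
    nm <- sum(is.na(assay(object, "exprs")))
    cat(sprintf(
        "MetaboCohort: %d variables x %d subjects (%d case [%s], %d control), %d missing cells\n",
        nrow(object), ncol(object), sum(g == cl), cl, sum(g != cl), nm))
})

setMethod("show", "CorrelationNetwork", function(object) {
    cat(sprintf(
        "CorrelationNetwork [%s]: %d nodes, %d edges (pairs; %d directed) | gates: |r|>%g, p<%g, FDR<%g\n",
        object@group, length(object@nodes), nrow(object@edges),
        2L * nrow(object@edges),
        object@gates["r_min"], object@gates["p_max"], object@gates["fdr_max"]))
})

setMethod("show", "SearchLedger", function(object) {
    cat(sprintf(
        "SearchLedger [%s, %d markers]: %d retained of %s evaluated (K = %d)\n",
        object@method, object@panelSize, nrow(object@models),
        format(object@nEvaluated, big.mark = ","), object@K))
    if (nrow(object@models)) {
        top <- object@models[1L, ]
        cat(sprintf("  best: %s (cv_auroc = %.3f)\n", top$panel, top$cv_auroc))
    }
})
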