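#' Construct a MetaboCohort
#'
#' Wraps a subjects-by-variables measurement matrix (with `NA` for missing
#' cells) and a two-level group label into a [MetaboCohort-class] object.
#'
#' @param values numeric matrix, one row per subject, one column per
#'   variable; column names identify variables, row names subjects.
#' @param group vector of group labels, length `nrow(values)`, with exactly
#'   two distinct values.
#' @param case_label which label denotes the case group. Defaults to
#'   `"ASD"` when present among the labels, otherwise the first label in
#'   order of appearance.
#' @param var_meta optional `data.frame` of per-variable annotation
#'   (e.g. a `source` column with the specimen type), `ncol(values)` rows.
#'
#' @return a [MetaboCohort-class].
#' @examples
#' m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
#' co <- MetaboCohort(m, rep(c("ASD", "TD"), each = 5))
#' isCase(co)
#' @export
MetaboCohort <- function(values, group, case_label = NULL, var_meta = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("var_%03d", seq_len(ncol(values)))
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
    group <- as.character(group)
    if (length(group) != nrow(values))
        stop("'group' must have one label per subject (row of 'values')")
    if (anyNA(group))
        stop("missing values are not allowed in the group column")
    labs <- unique(group)
    if (length(labs) != 2L)
        stop(sprintf("group column must have exactly two labels, found %d (%s)",
                     length(labs), paste(labs, collapse = ", ")))
    if (is.null(case_label))
        case_label <- if ("ASD" %in% labs) "ASD" else labs[1L]
    if (!case_label %in% labs)
        stop(sprintf("case_label '%s' is not among the group labels", case_label))
    rd <- if (is.null(var_meta)) DataFrame(row.names = colnames(values))
          else DataFrame(var_meta, row.names = colnames(values))
    se <- SummarizedExperiment(
        assays = list(exprs = t(values)),
        colData = DataFrame(group = group, row.names = rownames(values)),
        rowData = rd)
    metadata(se)$case_label <- case_label
    obj <- new("MetaboCohort", se)
    validObject(obj)
    obj
}

#' Cohort accessors
#'
#' `cohortValues()` returns the subjects-by-variables matrix (`NA` =
#' missing); `groupLabels()` the per-subject labels; `isCase()` a logical
#' vector marking case subjects; `varNames()` the variable identifiers;
#' `missingMask()` a logical subjects-by-variables matrix of missing cells.
#'
#' @param x a [MetaboCohort-class].
#' @name cohortValues
#' @aliases groupLabels isCase varNames missingMask
NULL

#' @rdname cohortValues
#' @export
setMethod("cohortValues", "MetaboCohort", function(x) t(assay(x, "exprs")))

#' @rdname cohortValues
#' @export
setMethod("groupLabels", "MetaboCohort", function(x)
    as.character(colData(x)$group))

#' @rdname cohortValues
#' @export
setMethod("isCase", "MetaboCohort", function(x)
    as.character(colData(x)$group) == metadata(x)$case_label)

#' @rdname cohortValues
#' @export
setMethod("varNames", "MetaboCohort", function(x) rownames(x))

#' @rdname cohortValues
#' @export
setMethod("missingMask", "MetaboCohort", function(x) is.na(cohortValues(x)))
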