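#' Read and write cohort tables
#'
#' Cohorts are stored as delimited text with a header row, a subject-ID
#' column, a group column and one numeric column per variable. Missing
#' cells are written as the empty string by default (`"NA"` optionally).
#' `writeCohort()` also writes a JSON sidecar (`<path>.meta.json`) with
#' the generation seed (when known), the case label and the column
#' conventions, so a written cohort is self-describing. Values are
#' written with 17 significant digits, making write-then-read an exact
#' round trip.
#'
#' @param cohort a [MetaboCohort-class].
#' @param path file path; extension `.csv` selects comma separation,
#'   anything else tab.
#' @param missing_as string used for missing cells (`""` or `"NA"`).
#' @param id_col,group_col column names used for subject IDs and labels.
#' @return `readCohort()` returns a [MetaboCohort-class];
#'   `writeCohort()` returns `path` invisibly.
#' @export
writeCohort <- function(cohort, path, missing_as = c("", "NA"),
                        id_col = "subject_id", group_col = "group") {
    stopifnot(is(cohort, "MetaboCohort"))
    missing_as <- match.arg(missing_as)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    V <- cohortValues(cohort)
    chr <- matrix(formatC(V, digits = 17, format = "g"), nrow(V), ncol(V),
                  dimnames = dimnames(V))
    chr[is.na(V)] <- missing_as
    out <- data.frame(rownames(V), groupLabels(cohort), chr,
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(out)[1:2] <- c(id_col, group_col)
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    spec <- metadata(cohort)$spec
    sidecar <- list(case_label = metadata(cohort)$case_label,
                    id_col = id_col, group_col = group_col,
                    missing_as = missing_as,
                    n_subjects = nrow(V), n_vars = ncol(V))
    if (!is.null(spec)) sidecar$seed <- spec@seed
    jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' @rdname writeCohort
#' @param case_label which group label is the case group; defaults to the
#'   sidecar value when present, else `"ASD"`/first label (see
#'   [MetaboCohort()]).
#' @export
readCohort <- function(path, id_col = "subject_id", group_col = "group",
                       case_label = NULL) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                            colClasses = "character", check.names = FALSE,
                            na.strings = character())
    if (!group_col %in% names(df))
        stop(sprintf("group column '%s' not found in %s", group_col, path))
    if (!id_col %in% names(df))
        stop(sprintf("subject-ID column '%s' not found in %s", id_col, path))
    vars <- names(df)[!names(df) %in% c(id_col, group_col)]
    if (anyDuplicated(vars))
        stop(sprintf("duplicate variable names: %s",
                     paste(unique(vars[duplicated(vars)]), collapse = ", ")))
    g <- df[[group_col]]
    if (anyNA(g) || any(g == ""))
        stop(sprintf("missing values in group column '%s'", group_col))
    if (length(unique(g)) != 2L)
        stop(sprintf("group column '%s' must have exactly two labels, found %d (%s)",
                     group_col, length(unique(g)),
                     paste(unique(g), collapse = ", ")))
    V <- matrix(NA_real_, nrow(df), length(vars),
                dimnames = list(df[[id_col]], vars))
    for (v in vars) {
        cell <- df[[v]]
        empty <- cell == "" | cell == "NA"
        num <- suppressWarnings(as.numeric(cell))
        bad <- which(!empty & is.na(num))
        if (length(bad))
            stop(sprintf("non-numeric cell in variable '%s' (row %d): '%s'",
                         v, bad[1L], cell[bad[1L]]))
        num[empty] <- NA_real_
        V[, v] <- num
    }
    meta_path <- paste0(path, ".meta.json")
    if (is.null(case_label) && file.exists(meta_path)) {
        side <- jsonlite::read_json(meta_path)
        case_label <- side$case_label
        if (!is.null(case_label) && !case_label %in% g) case_label <- NULL
    }
    MetaboCohort(V, group = g, case_label = case_label)
}
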