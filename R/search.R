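# ---- panel evaluation and ledger search ----

# Completed data matrices for the candidate variables: a single matrix
# when the columns are complete, otherwise one per imputation.
.search_matrices <- function(cohort, candidates, plan, n_imputations) {
    V <- cohortValues(cohort)[, candidates, drop = FALSE]
    if (!anyNA(V)) return(list(V))
    sub <- MetaboCohort(V, group = groupLabels(cohort),
                        case_label = metadata(cohort)$case_label)
    plan <- plan %||% imputationPlan()
    plan$n_imputations <- as.integer(n_imputations %||% plan$n_imputations)
    lapply(imputeCohort(sub, plan), cohortValues)
}

# Evaluate one panel over a list of completed matrices; metrics averaged
# across imputations, operating point taken on the pooled held-out scores.
.evaluate_panel <- function(mats, cols, is_case, method, cost = 1,
                            standardize = TRUE) {
    fitted <- cv <- acc_tr <- acc_cv <- numeric(length(mats))
    pooled <- numeric(length(is_case))
    for (m in seq_along(mats)) {
        X <- mats[[m]][, cols, drop = FALSE]
        if (method == "fda") {
            fit <- .fda_direction(X, is_case)
            sc <- as.numeric(X %*% fit$w)
            fitted[m] <- auroc_raw(sc[is_case], sc[!is_case])
            ho <- .fda_loocv_scores(X, is_case)
            cv[m] <- auroc_raw(ho[is_case], ho[!is_case])
            acc_tr[m] <- NA_real_
            acc_cv[m] <- NA_real_
        } else {
            f <- fitSvmPanel(X, is_case, cost = cost, standardize = standardize)
            acc_tr[m] <- f$train_accuracy
            dv <- attr(.svm_predict(f$model, X, decision.values = TRUE),
                       "decision.values")
            dec <- as.numeric(dv)
            if (colnames(dv) == "control/case") dec <- -dec
            lo <- .svm_loocv(X, is_case, cost, standardize)
            ho <- lo$scores
            fitted[m] <- auroc_raw(dec[is_case], dec[!is_case])
            cv[m] <- auroc_raw(ho[is_case], ho[!is_case])
            acc_cv[m] <- lo$accuracy
        }
        pooled <- pooled + ho / length(mats)
    }
    op <- operatingPoint(pooled, is_case)
    list(fitted_auroc = mean(fitted), cv_auroc = mean(cv),
         train_accuracy = mean(acc_tr), cv_accuracy = mean(acc_cv),
         sensitivity = unname(op["sensitivity"]),
         specificity = unname(op["specificity"]))
}

#' Evaluate a single biomarker panel
#'
#' Fits the panel on the full cohort and computes the leave-one-out
#' cross-validated performance: each subject is held out once, the model
#' is refit on the remaining subjects, and the held-out scores form the
#' CV ROC. When the panel variables contain missing cells, the whole
#' procedure runs once per completed (imputed) dataset and the metrics
#' are averaged; the operating point is taken on the
#' across-imputation-averaged held-out scores.
#'
#' @param cohort a [MetaboCohort-class].
#' @param panel character vector of variable names.
#' @param method `"fda"` or `"svm"` (linear kernel).
#' @param plan [imputationPlan()] used if imputation is needed.
#' @param n_imputations override of the plan's imputation count.
#' @param cost,standardize SVM settings (ignored for FDA).
#' @return list: `fitted_auroc`, `cv_auroc`, `train_accuracy`,
#'   `cv_accuracy` (SVM only, else `NA`), `sensitivity`, `specificity`.
#' @export
evaluatePanel <- function(cohort, panel, method = c("fda", "svm"),
                          plan = NULL, n_imputations = NULL,
                          cost = 1, standardize = TRUE) {
    method <- match.arg(method)
    stopifnot(all(panel %in% varNames(cohort)))
    mats <- .search_matrices(cohort, panel, plan, n_imputations)
    .evaluate_panel(mats, seq_along(panel), isCase(cohort), method,
                    cost = cost, standardize = standardize)
}

.new_ledger <- function(method, k, K, models, n_evaluated, info = list()) {
    if (nrow(models)) {
        ord <- order(-models$cv_auroc, -models$fitted_auroc, models$panel)
        if (method == "svm")
            ord <- order(-models$cv_accuracy, -models$cv_auroc, models$panel)
        models <- models[ord, , drop = FALSE]
        if (nrow(models) > K) models <- models[seq_len(K), , drop = FALSE]
        models$rank <- seq_len(nrow(models))
        rownames(models) <- NULL
    }
    new("SearchLedger", method = method, panelSize = as.integer(k),
        K = as.integer(K), models = models, nEvaluated = n_evaluated,
        info = info)
}

.empty_models <- function() {
    data.frame(panel = character(), fitted_auroc = numeric(),
               cv_auroc = numeric(), train_accuracy = numeric(),
               cv_accuracy = numeric(), sensitivity = numeric(),
               specificity = numeric(), stringsAsFactors = FALSE)
}

.eval_panel_set <- function(panels, mats, candidates, is_case, method,
                            K, k, cost = 1, standardize = TRUE,
                            accuracy_gate = NULL, info = list()) {
    rows <- vector("list", length(panels))
    n_gated <- 0L
    for (i in seq_along(panels)) {
        cols <- panels[[i]]
        if (!is.null(accuracy_gate)) {
            # SVM gate: training accuracy must clear the gate before the
            # panel earns its leave-one-out pass
            tr <- mean(vapply(mats, function(M) {
                fitSvmPanel(M[, cols, drop = FALSE], is_case, cost,
                            standardize)$train_accuracy
            }, numeric(1)))
            if (tr <= accuracy_gate) next
            n_gated <- n_gated + 1L
        }
        ev <- .evaluate_panel(mats, cols, is_case, method, cost, standardize)
        rows[[i]] <- data.frame(
            panel = paste(candidates[cols], collapse = "|"),
            fitted_auroc = ev$fitted_auroc, cv_auroc = ev$cv_auroc,
            train_accuracy = ev$train_accuracy, cv_accuracy = ev$cv_accuracy,
            sensitivity = ev$sensitivity, specificity = ev$specificity,
            stringsAsFactors = FALSE)
    }
    models <- do.call(rbind, c(list(.empty_models()), rows[!vapply(rows, is.null, TRUE)]))
    info$n_gated <- if (is.null(accuracy_gate)) NA_integer_ else n_gated
    .new_ledger(method, k, K, models, length(panels), info)
}

#' Exhaustive panel search
#'
#' Evaluates every size-`k` subset of the candidate variables
#' (`choose(length(candidates), k)` panels) by leave-one-out
#' cross-validated FDA and retains the top `K` by CV AUROC (ties broken
#' by fitted AUROC, then lexicographic panel key). With missing cells, a
#' reduced number of imputations (`n_imputations_search`) is used during
#' ranking. `count_only = TRUE` skips evaluation and just records the
#' exact combinatorial counter.
#'
#' @param cohort a [MetaboCohort-class].
#' @param candidates candidate variable names (typically the
#'   screened-significant set).
#' @param k panel size.
#' @param K retention cap (default 1000).
#' @param method `"fda"` (see [exhaustiveSvmSearch()] for the gated SVM
#'   variant).
#' @param count_only enumerate without evaluating.
#' @param plan imputation plan for cohorts with missing cells.
#' @param n_imputations_search imputations used while ranking.
#' @return a [SearchLedger-class].
#' @export
exhaustiveSearch <- function(cohort, candidates, k, K = 1000L,
                             method = "fda", count_only = FALSE,
                             plan = NULL, n_imputations_search = 5L) {
    stopifnot(all(candidates %in% varNames(cohort)), k >= 1L,
              length(candidates) >= k)
    n_panels <- choose(length(candidates), k)
    info <- list(candidates = candidates)
    if (count_only)
        return(.new_ledger(method, k, K, .empty_models(), n_panels, info))
    mats <- .search_matrices(cohort, candidates, plan, n_imputations_search)
    combs <- utils::combn(length(candidates), k, simplify = FALSE)
    .eval_panel_set(combs, mats, candidates, isCase(cohort), method,
                    K, k, info = info)
}

#' Greedy extension of a panel ledger
#'
#' Extends every retained size-`k` panel by each candidate variable not
#' already in it, deduplicates the child panels (a child reachable from
#' several parents is evaluated once), evaluates each child by LOOCV and
#' retains the top `K`. When the parent ledger retains *all* size-`k`
#' panels, the child set equals the full exhaustive size-`k+1`
#' enumeration.
#'
#' @param ledger a [SearchLedger-class] of size-`k` panels.
#' @param cohort the cohort the ledger was built on.
#' @param candidates the candidate universe used for extension.
#' @inheritParams exhaustiveSearch
#' @return a [SearchLedger-class] of size-`k+1` panels.
#' @export
greedyExtend <- function(ledger, cohort, candidates = NULL, K = 1000L,
                         plan = NULL, n_imputations_search = 5L) {
    stopifnot(is(ledger, "SearchLedger"), nrow(ledger@models) > 0L)
    candidates <- candidates %||% ledger@info$candidates
    stopifnot(!is.null(candidates))
    parents <- strsplit(ledger@models$panel, "|", fixed = TRUE)
    children <- new.env(parent = emptyenv())
    for (p in parents) {
        rest <- setdiff(candidates, p)
        if (!length(rest)) stop("no remaining variables to extend with")
        for (v in rest) {
            cols <- sort(match(c(p, v), candidates))
            assign(paste(cols, collapse = "."), cols, envir = children)
        }
    }
    panels <- mget(ls(children), envir = children)
    mats <- .search_matrices(cohort, candidates, plan, n_imputations_search)
    .eval_panel_set(unname(panels), mats, candidates, isCase(cohort),
                    ledger@method, K, ledger@panelSize + 1L,
                    info = list(candidates = candidates))
}

#' Exhaustive SVM panel search with an accuracy gate
#'
#' Fits every size-`panel_size` subset with a linear SVM; only panels
#' whose *training* accuracy exceeds `accuracy_gate` proceed to
#' leave-one-out cross-validation. Gated panels are ranked by LOOCV
#' accuracy (CV AUROC as tiebreaker). The ledger may be empty when no
#' panel clears the gate — a documented outcome on unstructured data.
#'
#' @inheritParams exhaustiveSearch
#' @param panel_size panel size (default 5; 4 also conventional).
#' @param accuracy_gate training-accuracy gate (default 0.90).
#' @param cost,standardize linear-SVM settings.
#' @return a [SearchLedger-class] with `info$n_gated` panels past the
#'   gate.
#' @export
exhaustiveSvmSearch <- function(cohort, candidates, panel_size = 5L,
                                accuracy_gate = 0.90, K = 1000L,
                                cost = 1, standardize = TRUE,
                                count_only = FALSE,
                                plan = NULL, n_imputations_search = 5L) {
    stopifnot(all(candidates %in% varNames(cohort)),
              length(candidates) >= panel_size, panel_size >= 2L,
              accuracy_gate > 0, accuracy_gate < 1)
    n_panels <- choose(length(candidates), panel_size)
    info <- list(candidates = candidates, accuracy_gate = accuracy_gate)
    if (count_only)
        return(.new_ledger("svm", panel_size, K, .empty_models(), n_panels, info))
    mats <- .search_matrices(cohort, candidates, plan, n_imputations_search)
    combs <- utils::combn(length(candidates), panel_size, simplify = FALSE)
    .eval_panel_set(combs, mats, candidates, isCase(cohort), "svm",
                    K, panel_size, cost = cost, standardize = standardize,
                    accuracy_gate = accuracy_gate, info = info)
}

#' Multi-size panel search
#'
#' Runs the staged search protocol over one candidate set: exhaustive
#' enumeration for panel sizes up to `exhaustive_max` (default 4), then
#' greedy extension of the retained ledger for larger sizes.
#'
#' @inheritParams exhaustiveSearch
#' @param sizes panel sizes to produce (contiguous, e.g. `2:6`).
#' @param exhaustive_max largest size searched exhaustively.
#' @return named list of [SearchLedger-class] objects (`"k2"`, `"k3"`, ...).
#' @export
searchPanels <- function(cohort, candidates, sizes = 2:5, K = 1000L,
                         exhaustive_max = 4L, plan = NULL,
                         n_imputations_search = 5L) {
    sizes <- sort(unique(as.integer(sizes)))
    ledgers <- list()
    prev <- NULL
    for (k in seq(min(sizes), max(sizes))) {
        led <- if (k <= exhaustive_max || is.null(prev))
            exhaustiveSearch(cohort, candidates, k, K, plan = plan,
                             n_imputations_search = n_imputations_search)
        else
            greedyExtend(prev, cohort, candidates, K, plan = plan,
                         n_imputations_search = n_imputations_search)
        prev <- led
        if (k %in% sizes) ledgers[[paste0("k", k)]] <- led
    }
    ledgers
}

#' Search variants: full, exclusion, complete-case
#'
#' Reruns the panel search under the protocol's three candidate regimes:
#' (a) the full candidate set; (b) with named variables excluded (e.g.
#' the dominant correlated marker pair, to surface the remaining
#' biomarkers); (c) restricted to candidates with zero missing cells,
#' with no imputation.
#'
#' @inheritParams searchPanels
#' @param exclude variable names removed in variant (b); if none are
#'   present the variant is skipped with a warning.
#' @return list of ledger lists: `full`, `excluded` (optional),
#'   `complete_case`.
#' @export
runVariants <- function(cohort, candidates, exclude = character(),
                        sizes = 2:5, K = 1000L, exhaustive_max = 4L,
                        plan = NULL, n_imputations_search = 5L) {
    out <- list(full = searchPanels(cohort, candidates, sizes, K,
                                    exhaustive_max, plan,
                                    n_imputations_search))
    if (length(exclude)) {
        present <- intersect(exclude, candidates)
        if (!length(present)) {
            warning("none of the exclusion variables are among the candidates; variant skipped")
        } else {
            out$excluded <- searchPanels(cohort, setdiff(candidates, present),
                                         sizes, K, exhaustive_max, plan,
                                         n_imputations_search)
        }
    }
    complete <- candidates[colSums(is.na(cohortValues(cohort)[, candidates,
                                                              drop = FALSE])) == 0L]
    if (length(complete) >= max(sizes))
        out$complete_case <- searchPanels(cohort, complete, sizes, K,
                                          exhaustive_max, plan = NULL,
                                          n_imputations_search = 1L)
    out
}

#' @rdname ledgerModels
#' @export
setMethod("ledgerModels", "SearchLedger", function(x) x@models)

#' Ledger accessors
#'
#' `ledgerModels()` returns the retained panel table; `nEvaluated()` the
#' exact number of panels the search evaluated (or enumerated, in
#' counting mode).
#'
#' @param x a [SearchLedger-class].
#' @name ledgerModels
#' @aliases nEvaluated
#' @export
setMethod("nEvaluated", "SearchLedger", function(x) x@nEvaluated)

#' Marker prevalence in a ledger
#'
#' Fraction of the retained top panels containing each variable. The
#' prevalences sum to the panel size.
#'
#' @param x a [SearchLedger-class].
#' @param top use only the first `top` retained models (default: all).
#' @param ... unused.
#' @return named numeric vector, descending.
#' @rdname markerPrevalence
#' @export
setMethod("markerPrevalence", "SearchLedger", function(x, top = NULL, ...) {
    m <- x@models
    if (!nrow(m)) return(stats::setNames(numeric(), character()))
    if (!is.null(top)) m <- m[seq_len(min(top, nrow(m))), , drop = FALSE]
    members <- unlist(strsplit(m$panel, "|", fixed = TRUE))
    tab <- sort(table(members) / nrow(m), decreasing = TRUE)
    stats::setNames(as.numeric(tab), names(tab))
})

#' Export a ledger as a delimited table
#'
#' @param ledger a [SearchLedger-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
exportLedger <- function(ledger, path) {
    utils::write.table(ledgerModels(ledger), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
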