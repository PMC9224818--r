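#' Pipeline run configuration
#'
#' Bundles every stage's settings into one object. Exactly one of
#' `input` (path to a cohort table) or `spec` (a [CohortSpec-class] for
#' synthetic data) must be provided. The global `seed` feeds the
#' imputation plan and (when `spec` is the `"study"` sentinel) the
#' synthetic generator.
#'
#' @param input path to a cohort file readable by [readCohort()], or
#'   `NULL`.
#' @param spec a [CohortSpec-class], `"study"` for the default study
#'   conditions, or `NULL`.
#' @param screen a [screenConfig()].
#' @param gates network gates (list with `r_min`, `p_max`, `fdr_max`,
#'   optional `r_display_min`).
#' @param plan an [imputationPlan()] (its seed is overridden by `seed`).
#' @param fda list of FDA search settings: `sizes`, `K`,
#'   `exhaustive_max`, `exclude`, `n_imputations_search`,
#'   `max_candidates` (candidates are the significant variables, trimmed
#'   to the top `max_candidates` by AUROC to bound the combinatorial
#'   cost), `variants` (run exclusion/complete-case variants).
#' @param svm list of SVM search settings: `panel_size`,
#'   `accuracy_gate`, `K`, `cost`, `max_candidates`.
#' @param candidate_override optional explicit candidate variable list,
#'   widening or replacing the significant set.
#' @param seed global seed.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(input = NULL, spec = "study",
                      screen = screenConfig(),
                      gates = list(r_min = 0.35, p_max = 0.05,
                                   fdr_max = 0.10, r_display_min = NULL),
                      plan = imputationPlan(n_imputations = 5L),
                      fda = list(sizes = 2:5, K = 1000L, exhaustive_max = 4L,
                                 exclude = character(),
                                 n_imputations_search = 5L,
                                 max_candidates = 15L, variants = FALSE),
                      svm = list(panel_size = 5L, accuracy_gate = 0.90,
                                 K = 1000L, cost = 1, max_candidates = 10L),
                      candidate_override = NULL,
                      seed = 1L) {
    if (!is.null(input) && !identical(spec, NULL) && !identical(spec, "study"))
        stop("provide either 'input' or 'spec', not both")
    if (is.null(input) && is.null(spec))
        stop("provide one of 'input' or 'spec'")
    if (!is.null(input)) spec <- NULL
    if (identical(spec, "study")) spec <- cohortSpec(seed = seed)
    plan$seed <- as.integer(seed)
    structure(list(input = input, spec = spec, screen = screen,
                   gates = gates, plan = plan, fda = fda, svm = svm,
                   candidate_override = candidate_override,
                   seed = as.integer(seed)),
              class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Maps a flat YAML file onto [runConfig()]. Recognized top-level keys:
#' `input`, `seed`, and the nested blocks `synthetic` (fields of
#' [cohortSpec()] except the structured ones), `screen`, `gates`,
#' `imputation`, `fda`, `svm`.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    seed <- as.integer(y$seed %||% 1L)
    spec <- if (!is.null(y$input)) NULL
            else if (is.null(y$synthetic)) "study"
            else do.call(cohortSpec, c(y$synthetic, list(seed = seed)))
    screen <- do.call(screenConfig, y$screen %||% list())
    plan <- do.call(imputationPlan, y$imputation %||% list(n_imputations = 5L))
    base <- runConfig(input = y$input, spec = spec %||% NULL,
                      screen = screen, plan = plan, seed = seed)
    for (blk in c("gates", "fda", "svm"))
        if (!is.null(y[[blk]]))
            base[[blk]] <- utils::modifyList(base[[blk]], y[[blk]])
    base
}

.stage_file <- function(dir, ...) file.path(dir, sprintf(...))

.load_cohort <- function(dir) {
    path <- .stage_file(dir, "cohort.tsv")
    if (!file.exists(path))
        stop(sprintf("missing upstream artifact: %s (run the simulate stage or provide an input cohort)", path))
    readCohort(path)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from files in the run directory produced
#' by earlier stages and writes its own artifacts there, so stages can
#' be re-run individually (deleting downstream artifacts and re-running
#' downstream stages reproduces them):
#'
#' * `pipelineSimulate()`: `cohort.tsv` (+ `.meta.json` sidecar) from
#'   `config$spec`, or copies the `config$input` cohort in.
#' * `pipelineScreen()`: `screen.tsv`, the Table-1-shaped univariate
#'   results, plus `screen_log.txt` with the per-variable routing.
#' * `pipelineNetwork()`: per-group gated edge tables
#'   (`network_case.tsv` / `network_control.tsv`), SIF exports and
#'   `network_contrast.json`.
#' * `pipelineImpute()`: completed cohorts `completed_###.tsv`.
#' * `pipelineSearchFda()`: ledgers `fda_<variant>_k<k>.tsv` and
#'   prevalence tables.
#' * `pipelineSearchSvm()`: `svm_k<size>.tsv` and its prevalence table.
#' * `pipelineReport()`: `summary.txt`, `config_echo.yaml`, `run.json`
#'   (provenance: config hash, seed, package version, timestamp).
#'
#' @param config a [runConfig()].
#' @param dir run directory.
#' @return the written artifact paths, invisibly.
#' @name pipelineStages
NULL

#' @rdname pipelineStages
#' @export
pipelineSimulate <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- .stage_file(dir, "cohort.tsv")
    if (!is.null(config$input)) {
        co <- readCohort(config$input)
        writeCohort(co, out)
    } else {
        writeCohort(generateCohort(config$spec), out)
    }
    invisible(out)
}

#' @rdname pipelineStages
#' @export
pipelineScreen <- function(config, dir) {
    co <- .load_cohort(dir)
    res <- screenCohort(co, config$screen)
    out <- .stage_file(dir, "screen.tsv")
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    log <- c(sprintf("variables_in: %d", length(varNames(co))),
             sprintf("significant: %d", sum(res$significant)),
             sprintf("not_significant: %d", sum(!res$significant)),
             sprintf("skipped_degenerate: %d", length(attr(res, "skipped"))),
             sprintf("%s -> %s", res$var_name, res$test_kind))
    writeLines(log, .stage_file(dir, "screen_log.txt"))
    invisible(out)
}

.pipeline_candidates <- function(config, dir) {
    scr <- utils::read.delim(.stage_file(dir, "screen.tsv"))
    cand <- config$candidate_override %||% scr$var_name[scr$significant]
    list(candidates = as.character(cand), screen = scr)
}

#' @rdname pipelineStages
#' @export
pipelineNetwork <- function(config, dir) {
    co <- .load_cohort(dir)
    cand <- .pipeline_candidates(config, dir)$candidates
    if (length(cand) < 2L) {
        writeLines("fewer than 2 significant variables; no network",
                   .stage_file(dir, "network_contrast.json"))
        return(invisible(NULL))
    }
    g <- config$gates
    nets <- list()
    for (grp in c("case", "control")) {
        edges <- pairwiseCorrelations(co, cand, group = grp)
        net <- buildNetwork(edges, g$r_min, g$p_max, g$fdr_max, nodes = cand)
        exportNetwork(net, .stage_file(dir, "network_%s.tsv", grp),
                      format = "edges", r_display_min = g$r_display_min)
        exportNetwork(net, .stage_file(dir, "network_%s.sif", grp),
                      format = "sif", r_display_min = g$r_display_min)
        nets[[grp]] <- net
    }
    contrast <- compareNetworks(nets$case, nets$control)
    contrast$degree_diff <- as.list(contrast$degree_diff)
    jsonlite::write_json(contrast, .stage_file(dir, "network_contrast.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}

#' @rdname pipelineStages
#' @export
pipelineImpute <- function(config, dir) {
    co <- .load_cohort(dir)
    if (!anyNA(cohortValues(co))) return(invisible(character()))
    done <- imputeCohort(co, config$plan)
    paths <- character(length(done))
    for (m in seq_along(done)) {
        paths[m] <- .stage_file(dir, "completed_%03d.tsv", m)
        writeCohort(done[[m]], paths[m])
    }
    invisible(paths)
}

#' @rdname pipelineStages
#' @export
pipelineSearchFda <- function(config, dir) {
    co <- .load_cohort(dir)
    pc <- .pipeline_candidates(config, dir)
    f <- config$fda
    cand <- pc$candidates
    if (length(cand) > f$max_candidates) {
        scr <- pc$screen
        ord <- scr$var_name[scr$significant][
            order(-scr$auroc[scr$significant])]
        cand <- head(ord, f$max_candidates)
    }
    if (length(cand) < min(f$sizes))
        stop("too few candidate variables for the FDA search")
    run_one <- function(cands, tag) {
        ledgers <- searchPanels(co, cands, sizes = f$sizes, K = f$K,
                                exhaustive_max = f$exhaustive_max,
                                plan = config$plan,
                                n_imputations_search = f$n_imputations_search)
        for (nm in names(ledgers)) {
            exportLedger(ledgers[[nm]],
                         .stage_file(dir, "fda_%s_%s.tsv", tag, nm))
            prev <- markerPrevalence(ledgers[[nm]])
            utils::write.table(
                data.frame(variable = names(prev), prevalence = prev),
                .stage_file(dir, "fda_%s_%s_prevalence.tsv", tag, nm),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
        ledgers
    }
    out <- list(full = run_one(cand, "full"))
    if (isTRUE(f$variants)) {
        if (length(intersect(f$exclude, cand)))
            out$excluded <- run_one(setdiff(cand, f$exclude), "nosulf")
        complete <- cand[colSums(is.na(cohortValues(co)[, cand,
                                                        drop = FALSE])) == 0L]
        if (length(complete) >= max(f$sizes))
            out$complete_case <- run_one(complete, "complete")
    }
    invisible(out)
}

#' @rdname pipelineStages
#' @export
pipelineSearchSvm <- function(config, dir) {
    co <- .load_cohort(dir)
    pc <- .pipeline_candidates(config, dir)
    s <- config$svm
    cand <- pc$candidates
    if (length(cand) > s$max_candidates) {
        scr <- pc$screen
        ord <- scr$var_name[scr$significant][
            order(-scr$auroc[scr$significant])]
        cand <- head(ord, s$max_candidates)
    }
    if (length(cand) < s$panel_size)
        stop("too few candidate variables for the SVM search")
    led <- exhaustiveSvmSearch(co, cand, panel_size = s$panel_size,
                               accuracy_gate = s$accuracy_gate, K = s$K,
                               cost = s$cost, plan = config$plan)
    exportLedger(led, .stage_file(dir, "svm_k%d.tsv", s$panel_size))
    prev <- markerPrevalence(led)
    utils::write.table(data.frame(variable = names(prev), prevalence = prev),
                       .stage_file(dir, "svm_k%d_prevalence.tsv", s$panel_size),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(led)
}

#' @rdname pipelineStages
#' @export
pipelineReport <- function(config, dir) {
    scr_path <- .stage_file(dir, "screen.tsv")
    lines <- c("MetaboPanels run summary", strrep("=", 24), "")
    if (file.exists(scr_path)) {
        scr <- utils::read.delim(scr_path)
        lines <- c(lines,
                   sprintf("variables screened: %d", nrow(scr)),
                   sprintf("significant (p < %g, FDR < %g): %d",
                           config$screen$p_threshold,
                           config$screen$fdr_threshold,
                           sum(scr$significant)),
                   sprintf("best univariate AUROC: %.3f", max(scr$auroc)))
    }
    cj <- .stage_file(dir, "network_contrast.json")
    if (file.exists(cj)) {
        ct <- jsonlite::read_json(cj)
        if (!is.null(ct$n_shared))
            lines <- c(lines,
                       sprintf("network pairs: shared %d, case-only %d, control-only %d",
                               ct$n_shared, ct$n_case_only, ct$n_control_only))
    }
    best <- NULL
    for (f in list.files(dir, pattern = "^fda_full_k[0-9]+\\.tsv$",
                         full.names = TRUE)) {
        led <- utils::read.delim(f)
        if (nrow(led)) {
            lines <- c(lines, sprintf(
                "top FDA %s panel: %s (fitted %.3f, CV %.3f, sens %.2f, spec %.2f)",
                sub("^.*_k", "", sub("\\.tsv$", "", f)), led$panel[1L],
                led$fitted_auroc[1L], led$cv_auroc[1L],
                led$sensitivity[1L], led$specificity[1L]))
            best <- max(best %||% 0, led$cv_auroc[1L])
        }
    }
    if (!is.null(best) && best < 0.6)
        lines <- c(lines, "NOTE: no reliable panels (top CV AUROC < 0.6)")
    writeLines(lines, .stage_file(dir, "summary.txt"))
    echo <- .stage_file(dir, "config_echo.yaml")
    cfg_list <- config
    cfg_list$spec <- if (is.null(config$spec)) NULL else
        list(n_case = config$spec@n_case, n_control = config$spec@n_control,
             n_vars = config$spec@n_vars, seed = config$spec@seed,
             n_planted = nrow(config$spec@planted),
             missing_rate = config$spec@missing_rate)
    yaml::write_yaml(unclass(cfg_list), echo)
    jsonlite::write_json(
        list(config_md5 = unname(tools::md5sum(echo)),
             seed = config$seed,
             package_version = as.character(utils::packageVersion("MetaboPanels")),
             r_version = R.version.string,
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
        .stage_file(dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
    invisible(.stage_file(dir, "summary.txt"))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: simulate/ingest, univariate screen,
#' correlation networks, imputation artifacts, FDA panel search, SVM
#' panel search, report. Only screened-significant variables feed the
#' network and search stages. A failing stage writes a `FAILED` marker
#' (retaining earlier artifacts) and aborts with the stage name.
#'
#' @param config a [runConfig()].
#' @param dir output run directory (created if needed).
#' @return `dir`, invisibly.
#' @export
runPipeline <- function(config, dir) {
    stages <- list(simulate = pipelineSimulate, screen = pipelineScreen,
                   network = pipelineNetwork, impute = pipelineImpute,
                   search_fda = pipelineSearchFda,
                   search_svm = pipelineSearchSvm, report = pipelineReport)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(stages)) {
        ok <- tryCatch({ stages[[nm]](config, dir); TRUE },
                       error = function(e) {
                           writeLines(sprintf("stage %s failed: %s", nm,
                                              conditionMessage(e)),
                                      file.path(dir, "FAILED"))
                           stop(sprintf("pipeline stage '%s' failed: %s",
                                        nm, conditionMessage(e)), call. = FALSE)
                       })
    }
    invisible(dir)
}
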