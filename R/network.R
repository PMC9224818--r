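# Vectorized Pearson r / p / n over all column pairs, pairwise complete.
.cor_pmat <- function(X) {
    R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
    N <- crossprod(!is.na(X))
    df <- pmax(N - 2, 1)
    tstat <- R * sqrt(df / pmax(1 - R^2, .Machine$double.eps))
    P <- 2 * stats::pt(-abs(tstat), df)
    P[N < 3] <- NA_real_
    R[N < 3] <- NA_real_
    list(r = R, p = P, n = N)
}

#' Pairwise correlations within a group
#'
#' Computes Pearson correlations between all unordered pairs of the given
#' variables for one group (or the combined cohort), with pairwise
#' complete-case handling of missing cells. p-values come from the
#' standard two-sided Pearson t test. The FDR of each pair is the
#' leave-one-out Benjamini-Hochberg procedure applied across pairs:
#' remove one subject of the group, recompute every pair's p-value, BH
#' across pairs, and keep each pair's worst q-value over the replicates
#' (the same stability aggregation as the univariate screen).
#'
#' @param cohort a [MetaboCohort-class].
#' @param variables variable names to correlate (default: all).
#' @param group `"case"`, `"control"` or `"combined"`.
#' @param loo_fdr when `FALSE`, plain BH on the full-group p-values.
#' @return `data.frame` of edges: `var_a`, `var_b`, `r`, `p_value`,
#'   `fdr`, `n_pairs`, `group`. Pairs with a constant variable or fewer
#'   than 3 complete cases are dropped (names in `attr(, "skipped")`).
#' @export
pairwiseCorrelations <- function(cohort, variables = NULL,
                                 group = c("case", "control", "combined"),
                                 loo_fdr = TRUE) {
    group <- match.arg(group)
    variables <- variables %||% varNames(cohort)
    if (length(variables) < 2L)
        stop("need at least 2 variables")
    V <- cohortValues(cohort)[, variables, drop = FALSE]
    keep <- switch(group, case = isCase(cohort),
                   control = !isCase(cohort),
                   combined = rep(TRUE, nrow(V)))
    X <- V[keep, , drop = FALSE]
    full <- .cor_pmat(X)
    ut <- upper.tri(full$r)
    idx <- which(ut, arr.ind = TRUE)
    fdr <- if (loo_fdr) {
        qmax <- rep(-Inf, nrow(idx))
        for (i in seq_len(nrow(X))) {
            p_i <- .cor_pmat(X[-i, , drop = FALSE])$p[ut]
            qmax <- pmax(qmax, bh_adjust(p_i))
        }
        qmax[!is.finite(qmax) & !is.na(qmax)] <- NA_real_
        qmax
    } else bh_adjust(full$p[ut])
    edges <- data.frame(
        var_a = variables[idx[, 1L]], var_b = variables[idx[, 2L]],
        r = full$r[ut], p_value = full$p[ut], fdr = fdr,
        n_pairs = full$n[ut], group = group, stringsAsFactors = FALSE)
    bad <- is.na(edges$r)
    skipped <- paste(edges$var_a[bad], edges$var_b[bad], sep = "~")
    if (any(bad))
        message(sprintf("pairwiseCorrelations: skipped %d degenerate pair(s)",
                        sum(bad)))
    edges <- edges[!bad, , drop = FALSE]
    rownames(edges) <- NULL
    attr(edges, "skipped") <- skipped
    edges
}

#' Build a thresholded correlation network
#'
#' Applies the three gates to an edge table from
#' [pairwiseCorrelations()]: `|r| > r_min`, `p < p_max`,
#' `fdr < fdr_max`.
#'
#' @param edges edge table from [pairwiseCorrelations()] (one group).
#' @param r_min,p_max,fdr_max the gates.
#' @param nodes node universe; defaults to all variables occurring in
#'   `edges`.
#' @return a [CorrelationNetwork-class].
#' @export
buildNetwork <- function(edges, r_min = 0.35, p_max = 0.05, fdr_max = 0.10,
                         nodes = NULL) {
    grp <- unique(edges$group)
    if (length(grp) > 1L)
        stop("edges must come from a single group")
    if (!length(grp)) grp <- "combined"
    nodes <- nodes %||% sort(unique(c(edges$var_a, edges$var_b)))
    pass <- !is.na(edges$r) & abs(edges$r) > r_min &
        !is.na(edges$p_value) & edges$p_value < p_max &
        !is.na(edges$fdr) & edges$fdr < fdr_max
    kept <- edges[pass, setdiff(names(edges), "group"), drop = FALSE]
    rownames(kept) <- NULL
    new("CorrelationNetwork", group = grp, nodes = as.character(nodes),
        edges = kept,
        gates = c(r_min = r_min, p_max = p_max, fdr_max = fdr_max))
}

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "CorrelationNetwork", function(x) x@edges)

#' Network accessors
#'
#' `networkEdges()` returns the gated edge table; `nodeDegrees()` the
#' per-node edge count over the node universe.
#'
#' @param x a [CorrelationNetwork-class].
#' @name networkEdges
#' @aliases nodeDegrees
#' @export
setMethod("nodeDegrees", "CorrelationNetwork", function(x) {
    d <- table(factor(c(x@edges$var_a, x@edges$var_b), levels = x@nodes))
    stats::setNames(as.integer(d), names(d))
})

.edge_keys <- function(net) {
    e <- networkEdges(net)
    if (!nrow(e)) return(character())
    paste(pmin(e$var_a, e$var_b), pmax(e$var_a, e$var_b), sep = "~")
}

#' Contrast two group networks
#'
#' Compares the case and control networks over a shared node universe:
#' counts of shared, case-only and control-only edges (unordered-pair
#' convention, with the doubled "directed" count alongside), per-node
#' degree differences, and a same-sign check on shared edges.
#'
#' @param net_case,net_control [CorrelationNetwork-class] objects.
#' @return list with elements `n_shared`, `n_case_only`,
#'   `n_control_only` (and `_directed` variants), `shared`, `case_only`,
#'   `control_only` (edge keys), `degree_diff` (case minus control) and
#'   `shared_same_sign` (fraction of shared edges with matching r sign).
#' @export
compareNetworks <- function(net_case, net_control) {
    kc <- .edge_keys(net_case)
    kt <- .edge_keys(net_control)
    shared <- intersect(kc, kt)
    co <- setdiff(kc, kt)
    to <- setdiff(kt, kc)
    nodes <- union(net_case@nodes, net_control@nodes)
    dc <- dt <- stats::setNames(integer(length(nodes)), nodes)
    dc[names(nodeDegrees(net_case))] <- nodeDegrees(net_case)
    dt[names(nodeDegrees(net_control))] <- nodeDegrees(net_control)
    same_sign <- NA_real_
    if (length(shared)) {
        rc <- stats::setNames(networkEdges(net_case)$r, kc)[shared]
        rt <- stats::setNames(networkEdges(net_control)$r, kt)[shared]
        same_sign <- mean(sign(rc) == sign(rt))
    }
    list(n_shared = length(shared),
         n_case_only = length(co), n_control_only = length(to),
         n_shared_directed = 2L * length(shared),
         n_case_only_directed = 2L * length(co),
         n_control_only_directed = 2L * length(to),
         shared = shared, case_only = co, control_only = to,
         degree_diff = dc - dt, shared_same_sign = same_sign)
}

#' Export a network for graph tools
#'
#' Writes either a delimited edge table (columns `var_a`, `var_b`,
#' `weight` = signed r, `p_value`, `fdr`, `n_pairs`; the sign supports
#' blue-positive/red-negative color mapping downstream) or a simple
#' interaction format (SIF) file (`var_a <pp|pn> var_b`, positive vs
#' negative correlation). An optional display threshold keeps only
#' `|r| > r_display_min` in the export without touching the analysis
#' gates.
#'
#' @param net a [CorrelationNetwork-class].
#' @param path output file.
#' @param format `"edges"` (TSV edge table) or `"sif"`.
#' @param r_display_min optional display-only |r| threshold (e.g. 0.40).
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("edges", "sif"),
                          r_display_min = NULL) {
    format <- match.arg(format)
    e <- networkEdges(net)
    if (!is.null(r_display_min))
        e <- e[abs(e$r) > r_display_min, , drop = FALSE]
    if (format == "edges") {
        out <- data.frame(var_a = e$var_a, var_b = e$var_b, weight = e$r,
                          p_value = e$p_value, fdr = e$fdr,
                          n_pairs = e$n_pairs, stringsAsFactors = FALSE)
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        lines <- if (nrow(e))
            sprintf("%s\t%s\t%s", e$var_a,
                    ifelse(e$r >= 0, "pp", "pn"), e$var_b)
        else character()
        writeLines(lines, path)
    }
    invisible(path)
}
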