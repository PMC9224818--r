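# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    code
}

# Error class used for degenerate per-variable inputs that screening skips.
degenerate_error <- function(msg) {
    structure(class = c("metabopanels_degenerate", "error", "condition"),
              list(message = msg, call = sys.call(-1L)))
}

# Raw AUROC A = P(case > control) + 0.5 P(tie), rank method with midranks.
auroc_raw <- function(case_values, control_values) {
    n1 <- length(case_values)
    n2 <- length(control_values)
    if (n1 < 1L || n2 < 1L)
        stop("both groups must be non-empty")
    r <- rank(c(case_values, control_values))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Benjamini-Hochberg over a vector that may contain NAs (skipped entries):
# NAs stay NA and do not count toward the number of hypotheses.
bh_adjust <- function(p) {
    ok <- !is.na(p)
    q <- rep(NA_real_, length(p))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}

# Center columns of M at mu without sweep() overhead.
center_cols <- function(M, mu) {
    M - matrix(mu, nrow(M), length(mu), byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
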