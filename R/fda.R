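# ---- Fisher discriminant analysis (two classes, closed form) ----

# Unit-norm discriminant direction w maximizing the Rayleigh quotient
# J(w) = (w' S_B w) / (w' S_W w); for two classes w is proportional to
# S_W^{-1} (mu_case - mu_control). S_W gets an eps-ridge
# (1e-6 * trace/k) so collinear panels stay solvable.
.fda_direction <- function(X, is_case, normalize = TRUE) {
    X1 <- X[is_case, , drop = FALSE]
    X0 <- X[!is_case, , drop = FALSE]
    mu1 <- colMeans(X1)
    mu0 <- colMeans(X0)
    S <- crossprod(center_cols(X1, mu1)) + crossprod(center_cols(X0, mu0))
    k <- ncol(X)
    # per-variable relative ridge: scale-equivariant (so rescaling a
    # variable leaves projection scores invariant), with an absolute
    # floor for within-group-constant variables
    ridge <- 1e-6 * diag(S)
    ridge[ridge == 0] <- 1e-12
    w <- as.numeric(solve(S + diag(ridge, k), mu1 - mu0))
    if (normalize) {
        # unit length for reporting; leave-one-out scoring keeps the raw
        # solution so fold scores share one scale convention
        nw <- sqrt(sum(w^2))
        if (nw > 0) w <- w / nw else w <- rep(1 / sqrt(k), k)
    }
    list(w = w, mu1 = mu1, mu0 = mu0)
}

#' Fit a Fisher discriminant model
#'
#' Two-class FDA in closed form: the discriminant direction maximizes
#' the ratio of between-class to within-class scatter, solved as
#' `S_W^-1 (mu_case - mu_control)` with a small ridge on `S_W` for
#' ill-conditioned (e.g. collinear) panels, and normalized to unit
#' length (the scale of the direction does not affect AUROC). Scores
#' are the projections `X w`, oriented so cases score higher on the
#' training data; the operating threshold maximizes Youden's J on the
#' fitted scores.
#'
#' @param X numeric matrix, subjects by panel variables (no missing
#'   values; impute first).
#' @param y logical (`TRUE` = case) or the cohort's two group labels.
#' @return object of class `FdaModel`: `panel`, `w` (unit direction),
#'   `mu_case`, `mu_control`, `threshold`, `fitted_scores`,
#'   `fitted_auroc`.
#' @export
fitFda <- function(X, y) {
    X <- as.matrix(X)
    if (ncol(X) < 1L) stop("panel must contain at least one variable")
    is_case <- if (is.logical(y)) y else y == y[1L] # caller orients
    if (length(unique(is_case)) != 2L)
        stop("both classes must be present")
    fit <- .fda_direction(X, is_case)
    scores <- as.numeric(X %*% fit$w)
    op <- operatingPoint(scores, is_case)
    structure(list(panel = colnames(X), w = fit$w,
                   mu_case = fit$mu1, mu_control = fit$mu0,
                   threshold = op["threshold"],
                   fitted_scores = scores,
                   fitted_auroc = auroc_raw(scores[is_case], scores[!is_case])),
              class = "FdaModel")
}

#' @export
print.FdaModel <- function(x, ...) {
    cat(sprintf("FdaModel: %d variables, fitted AUROC %.3f\n",
                length(x$w), x$fitted_auroc))
    invisible(x)
}

# Held-out FDA scores from leave-one-out refits.
.fda_loocv_scores <- function(X, is_case) {
    n <- nrow(X)
    scores <- numeric(n)
    for (i in seq_len(n)) {
        yi <- is_case[-i]
        if (length(unique(yi)) != 2L)
            stop("leave-one-out removes the last member of a class")
        w <- .fda_direction(X[-i, , drop = FALSE], yi, normalize = FALSE)$w
        scores[i] <- sum(X[i, ] * w)
    }
    scores
}

#' ROC operating point by Youden's J
#'
#' Sweeps every achievable threshold over the scores (classifying
#' `score >= threshold` as case) and returns the sensitivity/specificity
#' at the threshold maximizing Youden's J = TPR - FPR; ties break toward
#' higher sensitivity.
#'
#' @param scores numeric classifier scores (cases expected higher).
#' @param is_case logical labels.
#' @return named numeric: `sensitivity`, `specificity`, `threshold`.
#' @export
operatingPoint <- function(scores, is_case) {
    stopifnot(length(scores) == length(is_case),
              any(is_case), any(!is_case))
    u <- sort(unique(scores))
    cand <- c(u, max(u) + 1)  # thresholds at each score and above all
    best <- c(sensitivity = -1, specificity = -1, threshold = NA_real_)
    best_j <- -Inf
    for (thr in cand) {
        pred <- scores >= thr
        sens <- mean(pred[is_case])
        spec <- mean(!pred[!is_case])
        j <- sens + spec - 1
        if (j > best_j + 1e-12 ||
            (abs(j - best_j) <= 1e-12 && sens > best["sensitivity"])) {
            best_j <- j
            best <- c(sensitivity = sens, specificity = spec, threshold = thr)
        }
    }
    best
}
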