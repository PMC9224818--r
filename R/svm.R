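# ---- linear SVM panels (via e1071) ----

.svm_fit <- function(X, y_factor, cost, standardize) {
    # constant columns break scaling; drop them with a warning
    keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
    if (!all(keep)) {
        warning(sprintf("dropping constant variable(s): %s",
                        paste(colnames(X)[!keep], collapse = ", ")))
        X <- X[, keep, drop = FALSE]
    }
    if (ncol(X) == 0L) stop("no non-constant variables left")
    fit <- e1071::svm(x = X, y = y_factor, kernel = "linear", cost = cost,
                      scale = standardize, type = "C-classification")
    fit$metabopanels_keep <- keep
    fit
}

# predict helper honoring any dropped constant columns
.svm_predict <- function(fit, X, decision.values = FALSE) {
    keep <- fit$metabopanels_keep %||% rep(TRUE, ncol(X))
    stats::predict(fit, X[, keep, drop = FALSE],
                   decision.values = decision.values)
}

#' Fit a linear SVM on a biomarker panel
#'
#' Deterministic linear-kernel support vector classifier (no random
#' initialization), with variables standardized on the training split by
#' default. Training accuracy is the fraction of training subjects
#' classified correctly.
#'
#' @param X numeric matrix, subjects by panel variables (complete).
#' @param y logical (`TRUE` = case).
#' @param cost soft-margin cost parameter.
#' @param standardize scale variables to zero mean / unit variance.
#' @return list: `model` (the `e1071::svm` fit), `train_accuracy`.
#' @export
fitSvmPanel <- function(X, y, cost = 1, standardize = TRUE) {
    X <- as.matrix(X)
    yf <- factor(ifelse(y, "case", "control"), levels = c("case", "control"))
    if (length(unique(yf)) != 2L) stop("both classes must be present")
    fit <- .svm_fit(X, yf, cost, standardize)
    pred <- .svm_predict(fit, X)
    list(model = fit, train_accuracy = mean(pred == yf))
}

# Leave-one-out CV of a linear SVM: held-out predictions and decision
# values (oriented so cases score higher).
.svm_loocv <- function(X, y, cost, standardize) {
    n <- nrow(X)
    pred <- logical(n)
    dec <- numeric(n)
    yf <- factor(ifelse(y, "case", "control"), levels = c("case", "control"))
    for (i in seq_len(n)) {
        if (length(unique(yf[-i])) != 2L)
            stop("leave-one-out removes the last member of a class")
        fit <- .svm_fit(X[-i, , drop = FALSE], yf[-i], cost, standardize)
        p <- .svm_predict(fit, X[i, , drop = FALSE], decision.values = TRUE)
        d <- as.numeric(attr(p, "decision.values"))
        # e1071 orients decision values by the first training label seen
        if (colnames(attr(p, "decision.values")) == "control/case") d <- -d
        pred[i] <- p == "case"
        dec[i] <- d
    }
    list(accuracy = mean(pred == y), scores = dec)
}
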