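#' Build a confusion matrix
#'
#' Tallies observed against predicted classes into a
#' [ConfusionMatrix-class] with rows = observed, columns = predicted, in the
#' weakest-to-strongest class order.
#'
#' @param observed observed classes: a labelled \code{FingerprintSet}, a
#'   factor, or 1-based integer class indices.
#' @param predicted predicted classes, same length and scheme.
#' @param classNames ordered class names; inferred from \code{observed} when
#'   it is a \code{FingerprintSet} or factor.
#' @return a \code{ConfusionMatrix}.
#' @examples
#' cm <- confusion(c(1, 2, 2), c(1, 2, 1), classNames = binaryClasses())
#' counts(cm)
#' @export
confusion <- function(observed, predicted, classNames = NULL) {
    if (is(observed, "FingerprintSet")) {
        if (is.null(classNames)) classNames <- classNames(observed)
        observed <- labelIndices(observed)
    } else if (is.factor(observed)) {
        if (is.null(classNames)) classNames <- levels(observed)
        observed <- as.integer(observed)
    }
    if (is.factor(predicted)) predicted <- as.integer(predicted)
    if (is.character(predicted)) predicted <- match(predicted, classNames)
    observed <- as.integer(observed); predicted <- as.integer(predicted)
    if (length(observed) != length(predicted))
        stop("observed and predicted must have equal length")
    if (is.null(classNames))
        classNames <- paste0("class", seq_len(max(observed, predicted)))
    k <- length(classNames)
    if (any(c(observed, predicted) < 1L) || any(c(observed, predicted) > k))
        stop("class index out of range")
    cnt <- matrix(0L, k, k, dimnames = list(observed = classNames,
                                            predicted = classNames))
    tab <- table(factor(observed, levels = seq_len(k)),
                 factor(predicted, levels = seq_len(k)))
    cnt[] <- as.integer(tab)
    new("ConfusionMatrix", counts = cnt, classNames = classNames)
}

#' @rdname confusion
#' @param x a \code{ConfusionMatrix}.
#' @export
counts <- function(x) x@counts

#' @describeIn confusion print the counts with class names.
#' @param object a \code{ConfusionMatrix}.
#' @export
setMethod("show", "ConfusionMatrix", function(object) {
    cat("ConfusionMatrix (observed x predicted)\n")
    print(object@counts)
    invisible(NULL)
})

.asCounts <- function(cm) {
    if (is(cm, "ConfusionMatrix")) cm@counts else as.matrix(cm)
}

#' Balanced accuracy
#'
#' The mean of the per-class recalls,
#' \eqn{BA = (1/n) \sum_i TP_i / (TP_i + FN_i)}, where \eqn{TP_i} is the
#' diagonal entry of class \eqn{i} and \eqn{FN_i} its off-diagonal row sum.
#' Well suited to the severely imbalanced activity datasets this package
#' targets: a classifier that predicts a single class for everything scores
#' exactly \eqn{1/n} regardless of the imbalance.
#'
#' @param cm a [ConfusionMatrix-class] or square counts matrix with every
#'   observed class represented (positive row sums).
#' @return balanced accuracy in \[0, 1\].
#' @examples
#' cm <- confusion(c(1, 1, 2, 2), c(1, 2, 2, 2), classNames = binaryClasses())
#' balancedAccuracy(cm)
#' @export
balancedAccuracy <- function(cm) {
    m <- .asCounts(cm)
    rs <- rowSums(m)
    if (any(rs == 0))
        stop("no observed substances in class(es): ",
             paste(rownames(m)[rs == 0], collapse = ", "))
    mean(diag(m) / rs)
}

#' Per-class recall
#'
#' Recall (sensitivity) of each class: the diagonal entry divided by the row
#' sum, in class order.
#'
#' @inheritParams balancedAccuracy
#' @return numeric vector of per-class recalls.
#' @export
perClassRecall <- function(cm) {
    m <- .asCounts(cm)
    rs <- rowSums(m)
    if (any(rs == 0))
        stop("no observed substances in class(es): ",
             paste(rownames(m)[rs == 0], collapse = ", "))
    stats::setNames(diag(m) / rs, rownames(m))
}

#' Binary screening statistics
#'
#' Sensitivity (= recall of the Active class), specificity, precision and
#' recall for a two-class confusion matrix where the second class is the
#' stronger (Active) one. For a conservative screen the recall is the
#' critical figure: a missed active is costlier than a false alarm.
#' Balanced accuracy equals \code{(sensitivity + specificity) / 2}.
#'
#' @param cm a 2 x 2 [ConfusionMatrix-class] or counts matrix, rows/columns
#'   ordered (Inactive, Active).
#' @return named list with \code{sensitivity}, \code{specificity},
#'   \code{precision}, \code{recall}. When no substance is predicted Active
#'   the precision is undefined and returned as \code{NA} (never silently 0).
#' @export
binaryStats <- function(cm) {
    m <- .asCounts(cm)
    if (!all(dim(m) == c(2L, 2L))) stop("binaryStats needs a 2 x 2 matrix")
    tn <- m[1L, 1L]; fp <- m[1L, 2L]; fn <- m[2L, 1L]; tp <- m[2L, 2L]
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    list(sensitivity = sens, specificity = spec,
         precision = prec, recall = sens)
}

#' Matthews correlation coefficient
#'
#' The multi-class generalization of the MCC (the covariance form over the
#' confusion matrix), which reduces to the classical
#' \eqn{(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} for
#' two classes. A degenerate matrix (a single observed and single predicted
#' class) is defined as 0 with a warning.
#'
#' @inheritParams balancedAccuracy
#' @return value in \[-1, 1\].
#' @export
mcc <- function(cm) {
    m <- .asCounts(cm)
    s <- sum(m)
    truek <- rowSums(m)   # observed class totals
    predk <- colSums(m)   # predicted class totals
    c0 <- sum(diag(m))
    num <- c0 * s - sum(truek * predk)
    den <- sqrt(s^2 - sum(predk^2)) * sqrt(s^2 - sum(truek^2))
    if (den == 0) {
        warning("degenerate confusion matrix; MCC defined as 0")
        return(0)
    }
    num / den
}

#' Macro-averaged F-score
#'
#' Unweighted mean over classes of the one-vs-rest F-beta score (default
#' beta = 1, i.e. F1). Macro averaging gives each class equal weight, which
#' matters for imbalanced multi-class potency data. A class whose precision
#' and recall are both zero (or undefined) contributes 0 -- the convention
#' needed for split search on small nodes where a class is absent.
#'
#' @inheritParams balancedAccuracy
#' @param beta recall weight of the F-score; 1 gives the harmonic mean of
#'   precision and recall.
#' @return macro F in \[0, 1\].
#' @export
macroF <- function(cm, beta = 1) {
    m <- .asCounts(cm)
    k <- nrow(m)
    b2 <- beta^2
    f <- vapply(seq_len(k), function(i) {
        tp <- m[i, i]
        fp <- sum(m[, i]) - tp
        fn <- sum(m[i, ]) - tp
        den <- (1 + b2) * tp + b2 * fn + fp
        if (den == 0) 0 else (1 + b2) * tp / den
    }, 0)
    mean(f)
}

#' Applicability-domain coverage
#'
#' The fraction of evaluated substances falling inside the model's
#' applicability domain.
#'
#' @param inDomainFlags non-empty logical vector from [inDomain()].
#' @return coverage in \[0, 1\].
#' @export
coverage <- function(inDomainFlags) {
    if (!length(inDomainFlags)) stop("empty flag vector")
    mean(as.logical(inDomainFlags))
}
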