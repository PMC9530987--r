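#' Stratified train/test split
#'
#' Partitions substances into a training and a test set, preserving the class
#' proportions of imbalanced activity data: each class contributes
#' \code{floor(n_c * fraction)} substances to the training set, and the
#' remaining training slots (up to the global \code{floor(n * fraction)})
#' are assigned by largest fractional remainder, so every class's training
#' share is within one substance of \code{fraction}. With rare potency
#' classes (a handful of Strong actives in thousands of substances) an
#' unstratified split can leave a class unrepresented, making per-class test
#' metrics incomputable; stratification avoids that. A singleton class is
#' placed in the training set with a warning. Deterministic for a fixed seed.
#'
#' @param labels a \code{FingerprintSet} with labels, a factor, or an integer
#'   vector of class indices.
#' @param fraction training fraction in (0, 1); the conventional protocol
#'   trains on 75\% and validates on the remaining 25\%.
#' @param seed integer seed.
#' @return a [DatasetSplit-class].
#' @examples
#' sp <- stratifiedSplit(factor(rep(c("I", "A"), c(90, 10))), 0.75, seed = 1)
#' length(trainIndices(sp))
#' @export
stratifiedSplit <- function(labels, fraction = 0.75, seed = 1L) {
    idx <- .asLabelIdx(labels)
    if (!length(idx)) stop("empty label set")
    if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
    n <- length(idx)
    nTrainTotal <- floor(n * fraction)
    classes <- sort(unique(idx))
    perClass <- split(seq_len(n), idx)
    base <- vapply(perClass, function(i) floor(length(i) * fraction), 0)
    frac <- vapply(perClass, function(i) length(i) * fraction, 0) - base
    singleton <- vapply(perClass, length, 0L) == 1L
    if (any(singleton)) {
        warning("class(es) with a single member assigned to the training set: ",
                paste(classes[singleton], collapse = ", "))
        base[singleton] <- 1L
        frac[singleton] <- 0
    }
    extra <- nTrainTotal - sum(base)
    take <- base
    if (extra > 0) {
        ord <- order(frac, decreasing = TRUE)
        bump <- ord[seq_len(min(extra, sum(frac > 0)))]
        take[bump] <- take[bump] + 1L
    }
    train <- .withSeed(seed, {
        unlist(lapply(seq_along(perClass), function(ci) {
            i <- perClass[[ci]]
            if (length(i) == 1L) return(i)
            sample(i, size = min(take[ci], length(i)))
        }), use.names = FALSE)
    })
    train <- sort(as.integer(train))
    test <- setdiff(seq_len(n), train)
    new("DatasetSplit", train = train, test = as.integer(test),
        n = as.integer(n), seed = as.integer(seed))
}

.asLabelIdx <- function(labels) {
    if (is(labels, "FingerprintSet")) {
        idx <- labelIndices(labels)
        if (is.null(idx)) stop("FingerprintSet has no labels")
        idx
    } else if (is.factor(labels)) as.integer(labels)
    else as.integer(labels)
}

#' @rdname stratifiedSplit
#' @param x a \code{DatasetSplit}.
#' @export
trainIndices <- function(x) x@train

#' @rdname stratifiedSplit
#' @export
testIndices <- function(x) x@test

#' @describeIn stratifiedSplit display split sizes.
#' @param object a \code{DatasetSplit}.
#' @export
setMethod("show", "DatasetSplit", function(object) {
    cat("DatasetSplit:", length(object@train), "train /",
        length(object@test), "test of", object@n,
        "(seed", paste0(object@seed, ")"), "\n")
    invisible(NULL)
})

#' Filter substances by minimum number of data sources
#'
#' Literature-derived activity calls become markedly more reliable as the
#' number of independent sources grows; screening datasets are therefore
#' commonly restricted to substances supported by at least four sources.
#' Returns the indices (original order) of substances whose source count
#' meets the threshold. Idempotent: filtering an already-filtered vector
#' removes nothing further.
#'
#' @param counts non-negative integer source counts, or a
#'   \code{FingerprintSet} carrying them.
#' @param k minimum number of sources (default 4).
#' @return integer indices with \code{counts >= k}.
#' @examples
#' filterMinSources(c(5, 3, 4, 1), k = 4)
#' @export
filterMinSources <- function(counts, k = 4L) {
    if (is(counts, "FingerprintSet")) {
        counts <- sourceCounts(counts)
        if (is.null(counts)) stop("FingerprintSet has no source counts")
    }
    if (k < 0) stop("k must be >= 0")
    which(counts >= k)
}

#' Remove duplicated substances by canonical structure
#'
#' Given already-canonicalized structure strings (standardization itself is
#' the caller's concern), keeps the first occurrence of each structure.
#' When activity labels are supplied and duplicates disagree, the kept
#' substance is assigned the strongest label among its duplicates --
#' consistent with the conservative philosophy of never downgrading observed
#' activity.
#'
#' @param ids character vector of canonical structure strings.
#' @param labels optional integer class indices (1 = weakest) aligned with
#'   \code{ids}.
#' @return list with \code{keep} (indices of first occurrences),
#'   \code{nRemoved}, and \code{labels} (resolved labels for the kept
#'   substances, or \code{NULL}).
#' @examples
#' dedupSubstances(c("A", "B", "A"))$keep
#' @export
dedupSubstances <- function(ids, labels = NULL) {
    keep <- which(!duplicated(ids))
    res <- NULL
    if (!is.null(labels)) {
        labels <- as.integer(labels)
        resolved <- vapply(ids[keep], function(s) {
            max(labels[ids == s])
        }, 0L, USE.NAMES = FALSE)
        res <- as.integer(resolved)
    }
    list(keep = keep, nRemoved = length(ids) - length(keep), labels = res)
}
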