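#' Train a conservative random forest
#'
#' Trains an ensemble of decision trees (101 by default), each on an
#' independently drawn random subset of the training substances
#' (without replacement, 75\% of the training set by default). Per-tree RNG
#' streams are derived from \code{(seed, tree index)}, so training is
#' reproducible and each tree is independent of how many trees precede it.
#' If a tree's subset misses a class it is redrawn (up to 10 times), then
#' used as-is with a warning.
#'
#' @param x training data: \code{FingerprintSet} (labelled) or numeric
#'   substances x descriptors matrix.
#' @param y integer class indices when \code{x} is a matrix.
#' @param kind per-descriptor kind flags when \code{x} is a matrix.
#' @param classNames ordered class names when \code{x} is a matrix.
#' @param nTrees number of trees (default 101).
#' @param config a [treeConfig()] list shared by all trees.
#' @param trainFractionPerTree fraction of substances drawn per tree.
#' @param seed integer master seed.
#' @return a [ConservativeForest-class], all trees enabled and uncapped.
#' @export
trainForest <- function(x, y = NULL, kind = NULL, classNames = NULL,
                        nTrees = 101L, config = treeConfig(),
                        trainFractionPerTree = 0.75, seed = 1L) {
    if (is(x, "FingerprintSet")) {
        if (is.null(y)) y <- labelIndices(x)
        if (is.null(kind)) kind <- descriptorKind(x)
        if (is.null(classNames)) classNames <- classNames(x)
        x <- fingerprintMatrix(x)
    }
    if (!length(y)) stop("no training data")
    y <- as.integer(y)
    if (is.null(classNames)) classNames <- paste0("class", seq_len(max(y)))
    k <- length(classNames)
    if (!all(seq_len(k) %in% y))
        stop("all classes must be represented in the training data")
    if (is.null(colnames(x)))
        colnames(x) <- paste0("descriptor", seq_len(ncol(x)))
    n <- nrow(x)
    nPer <- max(2L, floor(n * trainFractionPerTree))
    trees <- lapply(seq_len(nTrees), function(t) {
        st <- .deriveSeed(seed, t)
        sub <- .withSeed(st, {
            s <- sample.int(n, nPer)
            tries <- 0L
            while (length(unique(y[s])) < k && tries < 10L) {
                s <- sample.int(n, nPer)
                tries <- tries + 1L
            }
            s
        })
        if (length(unique(y[sub])) < k)
            warning("tree ", t, ": subset misses a class after 10 redraws")
        growTree(x[sub, , drop = FALSE], y[sub], kind = kind,
                 classNames = classNames, config = config,
                 seed = .deriveSeed(st, 1L))
    })
    new("ConservativeForest", trees = trees,
        enabled = rep(TRUE, nTrees),
        depthCap = rep(NA_integer_, nTrees),
        classNames = classNames, descriptorIds = colnames(x),
        config = config, trainFractionPerTree = trainFractionPerTree,
        seed = as.integer(seed))
}

#' Conservative majority vote
#'
#' Returns the class with the maximum tally; among tied maxima the
#' strongest (highest-ordered) class wins, so an even Inactive/Active split
#' yields Active and a Weak/Moderate tie yields Moderate. This is the
#' tie-break that makes the whole pipeline conservative: it trades false
#' positives for fewer false negatives.
#'
#' @param tally named or unnamed per-class vote counts, ordered weakest to
#'   strongest.
#' @return 1-based index of the winning class.
#' @examples
#' conservativeVote(c(Inactive = 50, Active = 50))  # -> 2 (Active)
#' @export
conservativeVote <- function(tally) {
    if (sum(tally) <= 0) stop("empty tally")
    .conservativeMajority(tally)
}

#' @rdname trainForest
#' @param forest a \code{ConservativeForest}.
#' @export
nTrees <- function(forest) length(forest@trees)

#' @rdname trainForest
#' @export
enabledTrees <- function(forest) forest@enabled

#' @rdname trainForest
#' @export
depthCaps <- function(forest) forest@depthCap

#' @rdname trainForest
#' @export
forestTrees <- function(forest) forest@trees

#' @describeIn trainForest display forest summary.
#' @param object a \code{ConservativeForest}.
#' @export
setMethod("show", "ConservativeForest", function(object) {
    caps <- object@depthCap
    cat("ConservativeForest:", length(object@trees), "trees (",
        sum(object@enabled), "enabled ) | cost", object@config$cost, "\n")
    cat("classes:", paste(object@classNames, collapse = " < "), "\n")
    cat("depth caps:", if (all(is.na(caps))) "none"
        else paste0(sum(!is.na(caps)), " capped"), "\n")
    invisible(NULL)
})

## Per-tree vote matrix (n x nTrees) of class indices under the forest's
## enabled flags and depth caps; disabled trees yield NA columns.
.forestVotes <- function(forest, X) {
    n <- nrow(X)
    votes <- matrix(NA_integer_, n, length(forest@trees))
    for (t in which(forest@enabled)) {
        votes[, t] <- predict(forest@trees[[t]], X,
                              depthCap = forest@depthCap[t])
    }
    votes
}

## Tally votes (k x n) and resolve each substance by conservative vote.
.voteTally <- function(votes, k) {
    n <- nrow(votes)
    tally <- matrix(0L, n, k)
    for (t in seq_len(ncol(votes))) {
        v <- votes[, t]
        if (all(is.na(v))) next
        tally[cbind(seq_len(n), v)] <- tally[cbind(seq_len(n), v)] + 1L
    }
    tally
}

#' Predict with a conservative random forest
#'
#' Collects each enabled tree's prediction (at its depth cap) and resolves
#' every substance by [conservativeVote()]. Descriptors are matched by
#' identifier; missing descriptors are an error.
#'
#' @param object a [ConservativeForest-class].
#' @param newdata numeric matrix or \code{FingerprintSet}.
#' @param ... unused.
#' @return integer class indices (1 = weakest).
#' @export
setMethod("predict", "ConservativeForest", function(object, newdata, ...) {
    X <- .alignDescriptors(newdata, object@descriptorIds)
    k <- length(object@classNames)
    tally <- .voteTally(.forestVotes(object, X), k)
    as.integer(max.col(tally, ties.method = "last"))
})

## ---- serialization ---------------------------------------------------

.forestToList <- function(forest) {
    list(format = "ConservativeRF-forest", version = 1L,
         classNames = forest@classNames,
         descriptorIds = forest@descriptorIds,
         config = forest@config,
         trainFractionPerTree = forest@trainFractionPerTree,
         seed = forest@seed,
         enabled = forest@enabled,
         depthCap = forest@depthCap,
         trees = lapply(forest@trees, .treeToList))
}

.forestFromList <- function(l) {
    cfg <- .configFromList(l$config)
    caps <- vapply(l$depthCap, function(v)
        if (is.null(v)) NA_integer_ else as.integer(v), 0L)
    new("ConservativeForest",
        trees = lapply(l$trees, .treeFromList),
        enabled = vapply(l$enabled, isTRUE, TRUE),
        depthCap = caps,
        classNames = as.character(unlist(l$classNames)),
        descriptorIds = as.character(unlist(l$descriptorIds)),
        config = cfg,
        trainFractionPerTree = as.numeric(l$trainFractionPerTree),
        seed = as.integer(l$seed))
}

#' Serialize a forest to/from a JSON model file
#'
#' The model envelope holds the config, class ordering, descriptor ids,
#' per-tree enabled flags and depth caps, and all trees. Serialization is
#' deterministic: identical models produce byte-identical files.
#'
#' @param forest a [ConservativeForest-class].
#' @param path file path.
#' @return \code{writeForestJSON}: the path, invisibly;
#'   \code{readForestJSON}: a \code{ConservativeForest}.
#' @export
writeForestJSON <- function(forest, path) {
    json <- jsonlite::toJSON(.forestToList(forest), auto_unbox = TRUE,
                             digits = I(17), null = "null", na = "null")
    writeLines(json, path, useBytes = TRUE)
    invisible(path)
}

#' @rdname writeForestJSON
#' @export
readForestJSON <- function(path) {
    .forestFromList(jsonlite::fromJSON(path, simplifyVector = FALSE))
}
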