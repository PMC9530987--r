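#' Tree-growing configuration
#'
#' Collects the tunable parameters of the bespoke decision-tree learner.
#'
#' @param cost split cost: \code{"gini"} (weighted child Gini impurity,
#'   minimized) or a classification metric of the split-induced labelling,
#'   maximized: \code{"ba"} (balanced accuracy), \code{"mcc"} (Matthews
#'   correlation), \code{"macro_f"} (macro F-score).
#' @param maxDepth depth limit of the grown tree (root = 0). Deliberately
#'   generous; the genetic optimizer is expected to rein depth in
#'   afterwards.
#' @param nFeatureSubset number of descriptors drawn (without replacement)
#'   at each node; \code{NULL} means \code{ceiling(sqrt(d))} of the
#'   available descriptors, the canonical random-forest default.
#' @param minNodeSize smallest node that may still be split.
#' @param nBins number of equal-width bins per continuous descriptor,
#'   computed once per tree from that tree's sample.
#' @param fBeta beta of the F-score cost.
#' @return a named list of class parameters.
#' @export
treeConfig <- function(cost = c("gini", "ba", "mcc", "macro_f"),
                       maxDepth = 20L, nFeatureSubset = NULL,
                       minNodeSize = 2L, nBins = 20L, fBeta = 1) {
    cost <- match.arg(cost)
    stopifnot(maxDepth >= 1L, is.null(nFeatureSubset) || nFeatureSubset >= 1L,
              minNodeSize >= 1L, nBins >= 2L)
    list(cost = cost, maxDepth = as.integer(maxDepth),
         nFeatureSubset = if (is.null(nFeatureSubset)) NULL
                          else as.integer(nFeatureSubset),
         minNodeSize = as.integer(minNodeSize), nBins = as.integer(nBins),
         fBeta = as.numeric(fBeta))
}

#' Equal-width bin boundaries for a continuous descriptor
#'
#' Splits the observed range of a continuous descriptor into \code{nBins}
#' equal-width bins and returns the internal boundaries, which are the only
#' candidate thresholds the tree tests for that descriptor. A molar-mass
#' descriptor spanning 50-250 with 20 bins yields boundaries 60, 70, ...,
#' 240: the binning effectively turns a continuous descriptor into 19
#' binary ones.
#'
#' @param values numeric sample of the descriptor (the tree's substances).
#' @param nBins number of bins (default 20).
#' @return strictly increasing boundaries strictly inside the sample range;
#'   empty when the descriptor is constant in this sample (unusable for
#'   splitting).
#' @examples
#' computeBins(c(50, 250))
#' @export
computeBins <- function(values, nBins = 20L) {
    if (!length(values)) stop("no values")
    r <- range(values)
    if (r[1] == r[2]) return(numeric(0))
    b <- r[1] + (r[2] - r[1]) * seq_len(nBins - 1L) / nBins
    b <- b[b > r[1] & b < r[2]]
    b[!duplicated(b)]
}

## Conservative majority: the class with the maximum count; ties go to the
## strongest (highest-indexed) class.
.conservativeMajority <- function(counts) {
    mx <- which(counts == max(counts))
    as.integer(unname(mx[length(mx)]))
}

## Metric of a candidate labelling given the k x k confusion counts,
## oriented so that higher is always better.
## - ba: mean recall over observed-present classes.
## - mcc: generalized covariance form; degenerate -> 0.
## - macro_f: mean one-vs-rest F-beta over all k classes, undefined -> 0.
## - gini handled separately from child count vectors.
.splitMetricFromConfusion <- function(cost, m, fBeta = 1) {
    if (cost == "ba") {
        rs <- rowSums(m)
        keep <- rs > 0
        return(mean(diag(m)[keep] / rs[keep]))
    }
    if (cost == "mcc") {
        s <- sum(m)
        truek <- rowSums(m); predk <- colSums(m)
        num <- sum(diag(m)) * s - sum(truek * predk)
        den <- sqrt(s^2 - sum(predk^2)) * sqrt(s^2 - sum(truek^2))
        return(if (den == 0) 0 else num / den)
    }
    ## macro_f
    b2 <- fBeta^2
    k <- nrow(m)
    f <- vapply(seq_len(k), function(i) {
        tp <- m[i, i]
        fp <- sum(m[, i]) - tp
        fn <- sum(m[i, ]) - tp
        den <- (1 + b2) * tp + b2 * fn + fp
        if (den == 0) 0 else (1 + b2) * tp / den
    }, 0)
    mean(f)
}

## Oriented score of a two-child candidate given per-class count vectors of
## the left and right children. For gini: negative weighted child impurity.
## For metric costs: each child's samples are assigned the child's
## conservative-majority class and the metric of that induced labelling
## against the observed classes is returned.
.scoreSplit <- function(cost, leftCounts, rightCounts, fBeta = 1) {
    nl <- sum(leftCounts); nr <- sum(rightCounts)
    if (cost == "gini") {
        gl <- 1 - sum((leftCounts / nl)^2)
        gr <- 1 - sum((rightCounts / nr)^2)
        return(-(nl * gl + nr * gr) / (nl + nr))
    }
    k <- length(leftCounts)
    m <- matrix(0, k, k)
    m[, .conservativeMajority(leftCounts)] <-
        m[, .conservativeMajority(leftCounts)] + leftCounts
    m[, .conservativeMajority(rightCounts)] <-
        m[, .conservativeMajority(rightCounts)] + rightCounts
    .splitMetricFromConfusion(cost, m, fBeta)
}

## Oriented score of leaving the node unsplit (all samples assigned the
## node's conservative majority) -- the baseline a split must beat.
.scoreUnsplit <- function(cost, counts, fBeta = 1) {
    n <- sum(counts)
    if (cost == "gini") return(-(1 - sum((counts / n)^2)))
    k <- length(counts)
    m <- matrix(0, k, k)
    m[, .conservativeMajority(counts)] <- counts
    .splitMetricFromConfusion(cost, m, fBeta)
}

#' Exhaustive split cost of a candidate two-child partition
#'
#' Scores one candidate split under a chosen cost, oriented so that higher
#' is always better (Gini is negated). Metric costs score the labelling in
#' which each child's samples receive that child's conservative-majority
#' class. Exposed mainly for inspection and testing; [growTree()] uses the
#' same scoring internally.
#'
#' @param cost one of \code{"gini"}, \code{"ba"}, \code{"mcc"},
#'   \code{"macro_f"}.
#' @param y integer class indices (1-based) of the node's samples.
#' @param leftMask logical vector: which samples fall in the left child.
#' @param k number of classes.
#' @param fBeta F-score beta.
#' @return oriented score (higher better); \code{-Inf} for an empty child.
#' @export
splitCost <- function(cost, y, leftMask, k, fBeta = 1) {
    lc <- tabulate(y[leftMask], k)
    rc <- tabulate(y[!leftMask], k)
    if (sum(lc) == 0 || sum(rc) == 0) return(-Inf)
    .scoreSplit(cost, lc, rc, fBeta)
}

## Class counts per bin for one continuous descriptor restricted to a node:
## column g+1 holds the class counts of samples whose value lies in bin g
## (g = number of boundaries strictly below the value).
.binClassCounts <- function(xv, y, boundaries, k) {
    g <- findInterval(xv, boundaries, left.open = TRUE)
    cnt <- matrix(0L, k, length(boundaries) + 1L)
    tab <- table(factor(y, levels = seq_len(k)),
                 factor(g, levels = 0:length(boundaries)))
    cnt[] <- as.integer(tab)
    cnt
}

#' Best split at a node
#'
#' Draws a random subset of descriptors and exhaustively scores every
#' candidate split among them: binary descriptors at their single 0/1
#' split, continuous descriptors at each internal bin boundary of the
#' tree's [computeBins()] scheme. Returns the candidate with the best
#' oriented cost, breaking exact ties toward the lowest descriptor column
#' index and then the lowest threshold; returns \code{NULL} when no
#' candidate strictly improves on the unsplit node.
#'
#' @param idx integer indices of the node's samples (rows of \code{x}).
#' @param x numeric substances x descriptors matrix.
#' @param y integer class indices aligned with rows of \code{x}.
#' @param kind per-descriptor \code{"binary"}/\code{"continuous"} flags.
#' @param bins named list of boundaries per continuous descriptor column
#'   (names = column index as character), as prepared by [growTree()].
#' @param k number of classes.
#' @param config a [treeConfig()] list.
#' @return \code{list(feature, threshold, score)} or \code{NULL}.
#' @export
bestSplit <- function(idx, x, y, kind, bins, k, config) {
    d <- ncol(x)
    nsub <- config$nFeatureSubset
    if (is.null(nsub)) nsub <- ceiling(sqrt(d))
    feats <- sort(sample.int(d, size = min(nsub, d)))
    yv <- y[idx]
    baseline <- .scoreUnsplit(config$cost, tabulate(yv, k), config$fBeta)
    eps <- 1e-12
    best <- NULL
    bestScore <- baseline
    total <- tabulate(yv, k)
    for (j in feats) {
        xv <- x[idx, j]
        if (kind[j] == "binary") {
            lc <- tabulate(yv[xv <= 0.5], k)
            rc <- total - lc
            if (sum(lc) == 0 || sum(rc) == 0) next
            sc <- .scoreSplit(config$cost, lc, rc, config$fBeta)
            if (sc > bestScore + eps) {
                bestScore <- sc
                best <- list(feature = j, threshold = 0.5, score = sc)
            }
        } else {
            b <- bins[[as.character(j)]]
            if (!length(b)) next
            cnt <- .binClassCounts(xv, yv, b, k)
            cum <- cnt
            if (ncol(cnt) > 1L)
                cum <- t(apply(cnt, 1L, cumsum))
            for (t in seq_along(b)) {
                lc <- cum[, t]
                rc <- total - lc
                nl <- sum(lc)
                if (nl == 0 || nl == sum(total)) next
                sc <- .scoreSplit(config$cost, lc, rc, config$fBeta)
                if (sc > bestScore + eps) {
                    bestScore <- sc
                    best <- list(feature = j, threshold = b[t], score = sc)
                }
            }
        }
    }
    best
}

#' Grow a decision tree
#'
#' Recursively partitions the training substances by [bestSplit()] until a
#' node is pure, reaches \code{maxDepth}, falls below \code{minNodeSize},
#' or no candidate improves on leaving it unsplit. Continuous descriptors
#' are binned once per tree, from this tree's sample, before growing
#' starts. Every node (not only leaves) stores its class-count vector so
#' prediction can be truncated at any depth cap.
#'
#' @param x numeric substances x descriptors training matrix (or a
#'   \code{FingerprintSet}, in which case \code{y} and \code{kind} default
#'   to its labels and kind flags).
#' @param y integer class indices (1 = weakest).
#' @param kind per-descriptor kind flags.
#' @param classNames ordered class names.
#' @param config a [treeConfig()] list.
#' @param seed integer seed for the per-node feature subsets.
#' @return a [DecisionTree-class].
#' @export
growTree <- function(x, y = NULL, kind = NULL, classNames = NULL,
                     config = treeConfig(), seed = 1L) {
    if (is(x, "FingerprintSet")) {
        if (is.null(y)) y <- labelIndices(x)
        if (is.null(kind)) kind <- descriptorKind(x)
        if (is.null(classNames)) classNames <- classNames(x)
        x <- fingerprintMatrix(x)
    }
    stopifnot(nrow(x) == length(y))
    if (is.null(colnames(x)))
        colnames(x) <- paste0("descriptor", seq_len(ncol(x)))
    if (is.null(classNames))
        classNames <- paste0("class", seq_len(max(y)))
    if (is.null(kind))
        kind <- ifelse(apply(x, 2L, function(v) all(v %in% c(0, 1))),
                       "binary", "continuous")
    k <- length(classNames)
    y <- as.integer(y)
    contCols <- which(kind == "continuous")
    bins <- stats::setNames(
        lapply(contCols, function(j) computeBins(x[, j], config$nBins)),
        as.character(contCols))
    maxDepthReached <- 0L
    grow <- function(idx, depth) {
        cnts <- tabulate(y[idx], k)
        maxDepthReached <<- max(maxDepthReached, depth)
        nClassesHere <- sum(cnts > 0)
        if (depth >= config$maxDepth || nClassesHere <= 1L ||
            length(idx) < config$minNodeSize)
            return(list(leaf = TRUE, counts = cnts))
        sp <- bestSplit(idx, x, y, kind, bins, k, config)
        if (is.null(sp)) return(list(leaf = TRUE, counts = cnts))
        leftMask <- x[idx, sp$feature] <= sp$threshold
        list(leaf = FALSE, counts = cnts,
             feature = sp$feature,
             featureId = colnames(x)[sp$feature],
             threshold = sp$threshold,
             left = grow(idx[leftMask], depth + 1L),
             right = grow(idx[!leftMask], depth + 1L))
    }
    root <- .withSeed(seed, grow(seq_len(nrow(x)), 0L))
    new("DecisionTree", root = root, classNames = classNames,
        descriptorIds = colnames(x),
        bins = bins, config = config, depth = maxDepthReached)
}

#' @rdname growTree
#' @param x a \code{DecisionTree}.
#' @export
treeDepth <- function(x) x@depth

#' @describeIn growTree display tree summary.
#' @param object a \code{DecisionTree}.
#' @export
setMethod("show", "DecisionTree", function(object) {
    cat("DecisionTree: depth", object@depth, "| cost", object@config$cost,
        "| classes:", paste(object@classNames, collapse = " < "), "\n")
    invisible(NULL)
})

## Per-depth conservative-majority predictions for every row of X:
## an n x (treeDepth + 1) integer matrix whose column d+1 is the class each
## sample would receive if routing stopped at depth d. Samples reaching a
## leaf early keep that leaf's class in later columns.
.treePathPredictions <- function(tree, X) {
    depth <- tree@depth
    n <- nrow(X)
    M <- matrix(0L, n, depth + 1L)
    fill <- function(node, rows, d) {
        if (!length(rows)) return(invisible(NULL))
        cls <- .conservativeMajority(node$counts)
        if (node$leaf || d == depth) {
            M[rows, (d + 1L):(depth + 1L)] <<- cls
            return(invisible(NULL))
        }
        M[rows, d + 1L] <<- cls
        leftMask <- X[rows, node$feature] <= node$threshold
        fill(node$left, rows[leftMask], d + 1L)
        fill(node$right, rows[!leftMask], d + 1L)
    }
    fill(tree@root, seq_len(n), 0L)
    M
}

#' Predict with a decision tree
#'
#' Routes each substance down the tree until a leaf or the depth cap,
#' whichever comes first, and returns the conservative majority of the
#' stopping node's class counts (ties resolve to the stronger class). With
#' \code{depthCap = 0} every substance receives the root's conservative
#' majority.
#'
#' @param object a [DecisionTree-class].
#' @param newdata numeric matrix (substances x descriptors) or
#'   \code{FingerprintSet}; must provide every descriptor the tree
#'   references.
#' @param depthCap integer depth cap, or \code{NA} for uncapped prediction.
#' @param ... unused.
#' @return integer class indices (1 = weakest).
#' @export
setMethod("predict", "DecisionTree",
          function(object, newdata, depthCap = NA_integer_, ...) {
    X <- .alignDescriptors(newdata, object@descriptorIds)
    M <- .treePathPredictions(object, X)
    cap <- if (is.na(depthCap)) object@depth
           else min(as.integer(depthCap), object@depth)
    as.integer(M[, cap + 1L])
})

## Align prediction data to a model's descriptor space by id, erroring on
## missing descriptors.
.alignDescriptors <- function(newdata, ids) {
    X <- if (is(newdata, "FingerprintSet")) fingerprintMatrix(newdata)
         else as.matrix(newdata)
    if (!is.null(colnames(X))) {
        miss <- setdiff(ids, colnames(X))
        if (length(miss))
            stop("missing descriptor(s): ",
                 paste(utils::head(miss, 5L), collapse = ", "),
                 if (length(miss) > 5L) " ...")
        X <- X[, ids, drop = FALSE]
    } else if (ncol(X) != length(ids))
        stop("unnamed prediction matrix must have ", length(ids), " columns")
    if (anyNA(X)) stop("missing descriptor values in prediction data")
    X
}

## ---- JSON serialization ----------------------------------------------

.nodeToList <- function(node) {
    if (node$leaf)
        list(leaf = TRUE, counts = as.integer(node$counts))
    else
        list(leaf = FALSE, counts = as.integer(node$counts),
             feature = node$feature, featureId = node$featureId,
             threshold = node$threshold,
             left = .nodeToList(node$left), right = .nodeToList(node$right))
}

.nodeFromList <- function(l) {
    if (isTRUE(l$leaf))
        list(leaf = TRUE, counts = as.integer(unlist(l$counts)))
    else
        list(leaf = FALSE, counts = as.integer(unlist(l$counts)),
             feature = as.integer(l$feature),
             featureId = as.character(l$featureId),
             threshold = as.numeric(l$threshold),
             left = .nodeFromList(l$left), right = .nodeFromList(l$right))
}

.treeToList <- function(tree) {
    list(classNames = tree@classNames, descriptorIds = tree@descriptorIds,
         bins = tree@bins, config = tree@config, depth = tree@depth,
         root = .nodeToList(tree@root))
}

.configFromList <- function(cfg) {
    treeConfig(cost = as.character(cfg$cost),
               maxDepth = as.integer(cfg$maxDepth),
               nFeatureSubset = if (is.null(cfg$nFeatureSubset)) NULL
                                else as.integer(cfg$nFeatureSubset),
               minNodeSize = as.integer(cfg$minNodeSize),
               nBins = as.integer(cfg$nBins),
               fBeta = as.numeric(cfg$fBeta))
}

.treeFromList <- function(l) {
    cfg <- .configFromList(l$config)
    bins <- lapply(l$bins, function(b) as.numeric(unlist(b)))
    if (!length(bins)) bins <- stats::setNames(list(), character(0))
    new("DecisionTree", root = .nodeFromList(l$root),
        classNames = as.character(unlist(l$classNames)),
        descriptorIds = as.character(unlist(l$descriptorIds)),
        bins = bins, config = cfg, depth = as.integer(l$depth))
}

#' Serialize a decision tree to/from JSON
#'
#' Trees round-trip bit-exactly: thresholds are written at full precision
#' and \code{treeFromJSON(treeToJSON(t))} reconstructs an identical tree.
#'
#' @param tree a [DecisionTree-class].
#' @param json a JSON string produced by \code{treeToJSON}.
#' @return \code{treeToJSON}: a JSON string; \code{treeFromJSON}: a
#'   \code{DecisionTree}.
#' @export
treeToJSON <- function(tree) {
    as.character(jsonlite::toJSON(.treeToList(tree), auto_unbox = TRUE,
                                  digits = I(17), null = "null"))
}

#' @rdname treeToJSON
#' @export
treeFromJSON <- function(json) {
    .treeFromList(jsonlite::fromJSON(json, simplifyVector = FALSE))
}
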