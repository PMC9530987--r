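#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' FingerprintSet: substances-by-descriptors container
#'
#' A \code{FingerprintSet} holds the combined molecular fingerprint of a set of
#' substances together with optional activity labels and per-substance source
#' counts. It extends \link[SummarizedExperiment]{SummarizedExperiment}:
#' descriptors are the rows (features) and substances the columns (samples),
#' so the single assay \code{"fingerprints"} is a descriptors x substances
#' numeric matrix. Each descriptor carries a kind flag (\code{"binary"} for
#' 0/1 substructure bits, \code{"continuous"} for physical-chemical
#' properties) in \code{rowData}; labels and source counts live in
#' \code{colData}; the ordered class names (weakest to strongest activity) and
#' the labelling scheme live in \code{metadata}.
#'
#' Invariants enforced by the validity method: substance and descriptor
#' identifiers are unique, binary-flagged descriptors contain only 0/1 values,
#' no value is missing, and label indices fall inside the class set.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [FingerprintSet()] for the constructor,
#'   [fingerprintMatrix()], [activityLabels()], [sourceCounts()].
#' @export
setClass("FingerprintSet", contains = "SummarizedExperiment")

.validFingerprintSet <- function(object) {
    msg <- character()
    if (!"fingerprints" %in% assayNames(object))
        msg <- c(msg, "assay 'fingerprints' is missing")
    else {
        m <- assay(object, "fingerprints")
        if (anyNA(m))
            msg <- c(msg, "fingerprint values contain missing entries")
        if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
            msg <- c(msg, "descriptor ids must be present and unique")
        if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
            msg <- c(msg, "substance ids must be present and unique")
        kind <- rowData(object)$kind
        if (is.null(kind) || !all(kind %in% c("binary", "continuous")))
            msg <- c(msg, "rowData(x)$kind must be 'binary' or 'continuous' for every descriptor")
        else if (!anyNA(m)) {
            bin <- which(kind == "binary")
            if (length(bin) && ncol(m) &&
                !all(m[bin, , drop = FALSE] %in% c(0, 1)))
                msg <- c(msg, "binary-flagged descriptors must contain only 0/1")
        }
        cls <- metadata(object)$classNames
        if (is.null(cls) || length(cls) < 2L)
            msg <- c(msg, "metadata(x)$classNames must list >= 2 ordered classes")
        lab <- colData(object)$label
        if (!is.null(lab) && length(cls) &&
            !all(is.na(lab) | (lab >= 1L & lab <= length(cls))))
            msg <- c(msg, "labels out of range of classNames")
        sc <- colData(object)$sourceCount
        if (!is.null(sc) && any(!is.na(sc) & sc < 0))
            msg <- c(msg, "source counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
}
setValidity("FingerprintSet", .validFingerprintSet)

#' DatasetSplit: a seeded train/test partition
#'
#' Disjoint train and test index sets over \code{n} substances, produced by
#' [stratifiedSplit()]. The validity method asserts that the two sets are
#' disjoint and that their union covers every substance exactly once.
#'
#' @slot train integer vector of training indices.
#' @slot test integer vector of test indices.
#' @slot n total number of substances partitioned.
#' @slot seed integer seed the split was drawn with.
#' @export
setClass("DatasetSplit",
    representation(train = "integer", test = "integer",
                   n = "integer", seed = "integer"))

setValidity("DatasetSplit", function(object) {
    msg <- character()
    both <- c(object@train, object@test)
    if (length(intersect(object@train, object@test)))
        msg <- c(msg, "train and test overlap")
    if (!identical(sort(both), seq_len(object@n)))
        msg <- c(msg, "train and test must cover all substances exactly once")
    if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: observed-by-predicted class counts
#'
#' A k x k integer matrix of counts with observed classes as rows and
#' predicted classes as columns, in the weakest-to-strongest class order.
#' Build one with [confusion()]; feed it to [balancedAccuracy()],
#' [binaryStats()], [perClassRecall()], [mcc()] or [macroF()].
#'
#' @slot counts k x k matrix; \code{counts[i, j]} is the number of substances
#'   observed in class i and predicted in class j.
#' @slot classNames ordered class names (weakest first).
#' @export
setClass("ConfusionMatrix",
    representation(counts = "matrix", classNames = "character"))

setValidity("ConfusionMatrix", function(object) {
    msg <- character()
    k <- length(object@classNames)
    if (!all(dim(object@counts) == c(k, k)))
        msg <- c(msg, "counts must be k x k for k class names")
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
        msg <- c(msg, "counts must be non-negative integers")
    if (length(msg)) msg else TRUE
})

#' DecisionTree: a binary-test classification tree
#'
#' Internal nodes test one descriptor against one threshold (left branch:
#' value <= threshold; right: value > threshold); every node stores the
#' class-count vector of the training substances routed through it, so
#' prediction can stop early at any depth cap and return that node's
#' conservative majority. Continuous descriptors are discretized once per
#' tree into equal-width bins ([computeBins()]); binary descriptors are
#' tested at the single 0/1 split.
#'
#' @slot root nested-list node structure (see [growTree()]).
#' @slot classNames ordered class names, weakest first.
#' @slot descriptorIds descriptor identifiers of the training feature space.
#' @slot bins named list of internal bin boundaries per continuous descriptor.
#' @slot config the \code{treeConfig()} list used to grow the tree.
#' @slot depth depth actually reached (root = depth 0).
#' @export
setClass("DecisionTree",
    representation(root = "list", classNames = "character",
                   descriptorIds = "character", bins = "list",
                   config = "list", depth = "integer"))

#' ConservativeForest: an ensemble of decision trees with conservative voting
#'
#' An ordered collection of [DecisionTree-class] objects plus a per-tree
#' enabled flag and depth cap -- the genome the genetic optimizer
#' ([evolveForest()]) acts on. Prediction tallies the enabled trees' votes
#' (each tree read at its depth cap) and resolves ties toward the stronger
#' activity class ([conservativeVote()]).
#'
#' @slot trees list of \code{DecisionTree}.
#' @slot enabled logical, one flag per tree.
#' @slot depthCap integer per tree; \code{NA} means uncapped.
#' @slot classNames ordered class names, weakest first.
#' @slot descriptorIds descriptor identifiers the trees were trained on.
#' @slot config the shared \code{treeConfig()} list.
#' @slot trainFractionPerTree fraction of training substances drawn (without
#'   replacement) for each tree.
#' @slot seed integer master seed; per-tree streams are derived from it.
#' @export
setClass("ConservativeForest",
    representation(trees = "list", enabled = "logical", depthCap = "integer",
                   classNames = "character", descriptorIds = "character",
                   config = "list", trainFractionPerTree = "numeric",
                   seed = "integer"))

setValidity("ConservativeForest", function(object) {
    msg <- character()
    nt <- length(object@trees)
    if (length(object@enabled) != nt || length(object@depthCap) != nt)
        msg <- c(msg, "enabled and depthCap must have one entry per tree")
    if (nt && !any(object@enabled))
        msg <- c(msg, "at least one tree must be enabled")
    if (length(msg)) msg else TRUE
})

#' ADModel: density-kNN applicability domain on a PCA embedding
#'
#' Fitted by [fitAD()]: a PCA basis retaining enough components for >= 95%
#' (by default) of the fingerprint variance, the embedded training points,
#' each point's mean distance to its k nearest training neighbours (its
#' admission radius), and the n^(1/m) threshold parameterization that caps
#' those radii. A query is in-domain if it falls within the capped radius of
#' at least one training point ([inDomain()]).
#'
#' @slot center,rotation PCA centring vector and loading matrix
#'   (descriptors x components).
#' @slot varExplained cumulative explained-variance ratio of the retained
#'   components.
#' @slot embedding training points in PCA space (n x components).
#' @slot k neighbour count used for the per-point radii.
#' @slot radii uncapped per-point mean-kNN distances.
#' @slot m threshold exponent; the radius cap is the ceiling(n^(1/m))-th
#'   smallest per-point radius, so larger m tightens the domain.
#' @slot cap the derived global radius cap.
#' @slot descriptorIds descriptor identifiers of the fitting space.
#' @export
setClass("ADModel",
    representation(center = "numeric", rotation = "matrix",
                   varExplained = "numeric", embedding = "matrix",
                   k = "integer", radii = "numeric", m = "numeric",
                   cap = "numeric", descriptorIds = "character"))

setValidity("ADModel", function(object) {
    msg <- character()
    if (object@k >= nrow(object@embedding))
        msg <- c(msg, "k must be smaller than the number of training points")
    if (object@m <= 0) msg <- c(msg, "m must be positive")
    if (length(msg)) msg else TRUE
})
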