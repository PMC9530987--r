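#' Descriptor-generator adapters
#'
#' The fingerprint of a substance is the column-wise concatenation of the
#' outputs of one or more descriptor generators (structural fingerprint
#' bit-sets such as PubChem, MACCS, FP2/FP3/FP4, plus physical-chemical
#' properties). Computing those bits is the job of external chemistry
#' software; this package only defines the adapter contract and the
#' assembly step. An adapter is a list with:
#' \describe{
#'   \item{name}{prefix for the descriptor identifiers it contributes.}
#'   \item{width}{fixed output length per structure.}
#'   \item{kind}{\code{"binary"}/\code{"continuous"}, length 1 or width.}
#'   \item{fun}{\code{function(structures)} returning a length(structures)
#'     x width numeric matrix, with \code{NA} rows for structures it fails
#'     on.}
#' }
#' \code{makeHashBitAdapter} builds a self-contained test adapter that
#' derives \code{width} pseudo-random but deterministic bits from each
#' structure string by hashing -- no external tool needed, same contract.
#'
#' @param name adapter name.
#' @param width number of bits.
#' @return an adapter list.
#' @examples
#' ad <- makeHashBitAdapter("hash", 8)
#' ad$fun(c("CCO", "c1ccccc1"))
#' @export
makeHashBitAdapter <- function(name = "hash", width = 64L) {
    force(name); force(width)
    list(name = name, width = as.integer(width), kind = "binary",
         fun = function(structures) {
             t(vapply(structures, function(s) {
                 codes <- utf8ToInt(s)
                 h <- sum(codes * seq_along(codes) * 131) %% 2147483647
                 .withSeed(as.integer(h %% 1e7),
                           stats::rbinom(width, 1L, 0.5))
             }, numeric(width), USE.NAMES = FALSE))
         })
}

#' Assemble a combined fingerprint from adapters
#'
#' Runs each adapter over the structure list and concatenates the outputs
#' column-wise in the declared adapter order, prefixing descriptor
#' identifiers with the adapter name. Structures any adapter fails on
#' (\code{NA} in its output) are dropped with a warning -- never silently
#' zero-filled.
#'
#' @param structures character vector of canonical structure strings
#'   (e.g. SMILES); names, if present, become substance identifiers.
#' @param adapters list of adapters (see [makeHashBitAdapter()]).
#' @param ... passed to [FingerprintSet()] (e.g. \code{labels},
#'   \code{scheme}).
#' @return a \code{FingerprintSet} whose width is the sum of adapter
#'   widths.
#' @export
assembleFingerprints <- function(structures, adapters, ...) {
    ids <- names(structures)
    if (is.null(ids))
        ids <- paste0("substance", seq_along(structures), recycle0 = TRUE)
    blocks <- lapply(adapters, function(ad) {
        m <- ad$fun(as.character(structures))
        if (length(structures) == 0L)
            m <- matrix(numeric(0), 0L, ad$width)
        if (!is.matrix(m) || ncol(m) != ad$width)
            stop("adapter '", ad$name, "' returned wrong width")
        colnames(m) <- paste0(ad$name, "_", seq_len(ad$width))
        m
    })
    values <- do.call(cbind, blocks)
    kind <- unlist(lapply(adapters, function(ad)
        rep_len(ad$kind, ad$width)), use.names = FALSE)
    keep <- rowSums(is.na(values)) == 0
    if (!all(keep)) {
        warning(sum(!keep), " structure(s) dropped: adapter failure")
        values <- values[keep, , drop = FALSE]
        ids <- ids[keep]
    }
    if (length(ids)) rownames(values) <- ids
    FingerprintSet(values, descriptorKind = kind,
                   substanceIds = ids, ...)
}

#' Fingerprint pruning
#'
#' Two-step descriptor pruning applied before training: first remove
#' descriptors with no variance across the dataset, then remove one of
#' every pair of collinear descriptors (Pearson correlation above
#' \code{rMax}, default 0.98). Collinearity is scanned left-to-right in
#' descriptor order and the earlier descriptor of a collinear pair is
#' kept, which makes the result deterministic. By default the absolute
#' correlation is used (an anti-correlated bit carries the same
#' information); set \code{absolute = FALSE} for signed correlations only.
#' Both steps are idempotent, and the learned keep-list can be re-applied
#' to new data with [applyKeepList()] so that pruning is fit on training
#' data only.
#'
#' @param fp a \code{FingerprintSet}.
#' @return list with \code{fp} (pruned set) and \code{report}, a prune
#'   report list with \code{removedZeroVariance}, \code{removedCorrelated}
#'   (data.frame of kept/removed id and r), \code{nBefore}, \code{nAfter},
#'   \code{keep} (kept descriptor ids).
#' @examples
#' m <- cbind(a = c(0, 1, 0, 1), b = c(1, 1, 1, 1), c = c(0, 1, 0, 1))
#' pruneZeroVariance(FingerprintSet(m))$report$removedZeroVariance
#' @export
pruneZeroVariance <- function(fp) {
    m <- fingerprintMatrix(fp)
    if (!nrow(m)) stop("no substances")
    keep <- apply(m, 2L, function(v) length(unique(v)) > 1L)
    report <- list(removedZeroVariance = colnames(m)[!keep],
                   removedCorrelated = .emptyCorrRemovals(),
                   nBefore = ncol(m), nAfter = sum(keep),
                   keep = colnames(m)[keep])
    list(fp = fp[keep, ], report = report)
}

.emptyCorrRemovals <- function()
    data.frame(kept = character(0), removed = character(0),
               r = numeric(0), stringsAsFactors = FALSE)

#' @rdname pruneZeroVariance
#' @param rMax collinearity threshold; a pair with correlation above it is
#'   redundant.
#' @param absolute use |r| (default) rather than signed r.
#' @export
pruneCorrelated <- function(fp, rMax = 0.98, absolute = TRUE) {
    if (rMax <= 0 || rMax > 1) stop("rMax must be in (0, 1]")
    m <- fingerprintMatrix(fp)
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0))
        stop("zero-variance descriptors present; run pruneZeroVariance first")
    cr <- stats::cor(m)
    cmp <- if (absolute) abs(cr) else cr
    d <- ncol(m)
    keep <- rep(TRUE, d)
    removals <- vector("list", d)
    for (j in seq_len(d)) {
        if (!keep[j]) next
        if (j < d) {
            later <- which(keep & seq_len(d) > j)
            hits <- later[cmp[j, later] > rMax]
            if (length(hits)) {
                keep[hits] <- FALSE
                removals[[j]] <- data.frame(
                    kept = colnames(m)[j], removed = colnames(m)[hits],
                    r = cr[j, hits], stringsAsFactors = FALSE)
            }
        }
    }
    removed <- do.call(rbind, removals[!vapply(removals, is.null, TRUE)])
    if (is.null(removed)) removed <- .emptyCorrRemovals()
    rownames(removed) <- NULL
    report <- list(removedZeroVariance = character(0),
                   removedCorrelated = removed,
                   nBefore = d, nAfter = sum(keep),
                   keep = colnames(m)[keep])
    list(fp = fp[keep, ], report = report)
}

#' @rdname pruneZeroVariance
#' @param rZero drop also descriptors constant on this data before the
#'   collinearity scan (both steps in one call).
#' @export
pruneFingerprints <- function(fp, rMax = 0.98, absolute = TRUE,
                              rZero = TRUE) {
    step1 <- if (rZero) pruneZeroVariance(fp)
             else list(fp = fp,
                       report = list(removedZeroVariance = character(0)))
    step2 <- pruneCorrelated(step1$fp, rMax = rMax, absolute = absolute)
    report <- list(
        removedZeroVariance = step1$report$removedZeroVariance,
        removedCorrelated = step2$report$removedCorrelated,
        nBefore = if (rZero) step1$report$nBefore else step2$report$nBefore,
        nAfter = step2$report$nAfter,
        keep = step2$report$keep)
    list(fp = step2$fp, report = report)
}

#' @rdname pruneZeroVariance
#' @param keep character vector of descriptor ids learned on the training
#'   data (\code{report$keep}).
#' @export
applyKeepList <- function(fp, keep) {
    miss <- setdiff(keep, descriptorIds(fp))
    if (length(miss))
        stop("descriptor(s) absent from data: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    fp[keep, ]
}

#' Write a prune report as JSON
#'
#' @param report a prune report from [pruneFingerprints()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePruneReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(path)
}
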