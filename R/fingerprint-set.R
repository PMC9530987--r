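#' Construct a FingerprintSet
#'
#' Assembles the substances-by-descriptors fingerprint table, optional
#' activity labels and optional per-substance source counts into a validated
#' [FingerprintSet-class]. The input orientation follows the CSV dialect
#' (rows = substances); internally descriptors become the
#' SummarizedExperiment rows.
#'
#' @param values numeric matrix, substances x descriptors.
#' @param descriptorKind character vector, \code{"binary"} or
#'   \code{"continuous"} per descriptor. Defaults to calling every 0/1-valued
#'   column binary.
#' @param substanceIds,descriptorIds unique identifiers; taken from dimnames
#'   when omitted.
#' @param labels activity labels: a factor, character vector of class names,
#'   or 1-based integer indices into \code{classNames}. Optional.
#' @param classNames ordered class names, weakest to strongest. Defaults to
#'   \code{binaryClasses()} or \code{multiclass5Classes()} depending on
#'   \code{scheme}.
#' @param scheme labelling scheme, \code{"binary"} (Inactive/Active) or
#'   \code{"multiclass5"} (Inactive through Strong).
#' @param sourceCounts optional non-negative integers, one per substance.
#' @return a \code{FingerprintSet}.
#' @examples
#' m <- cbind(bit1 = c(0, 1, 1), bit2 = c(1, 1, 0), mw = c(120, 88, 240))
#' rownames(m) <- paste0("s", 1:3)
#' fps <- FingerprintSet(m, labels = c("Inactive", "Active", "Active"))
#' fps
#' @export
FingerprintSet <- function(values, descriptorKind = NULL,
                           substanceIds = rownames(values),
                           descriptorIds = colnames(values),
                           labels = NULL, classNames = NULL,
                           scheme = c("binary", "multiclass5"),
                           sourceCounts = NULL) {
    scheme <- match.arg(scheme)
    values <- as.matrix(values)
    if (is.null(substanceIds))
        substanceIds <- paste0("substance", seq_len(nrow(values)),
                               recycle0 = TRUE)
    if (is.null(descriptorIds))
        descriptorIds <- paste0("descriptor", seq_len(ncol(values)),
                                recycle0 = TRUE)
    if (is.null(classNames))
        classNames <- if (scheme == "binary") binaryClasses() else multiclass5Classes()
    if (is.null(descriptorKind)) {
        descriptorKind <- ifelse(
            apply(values, 2L, function(v) all(v %in% c(0, 1))),
            "binary", "continuous")
    }
    descriptorKind <- rep_len(descriptorKind, ncol(values))
    cd <- S4Vectors::DataFrame(row.names = substanceIds)
    if (!is.null(labels))
        cd$label <- .labelIndices(labels, classNames)
    if (!is.null(sourceCounts))
        cd$sourceCount <- as.integer(sourceCounts)
    se <- SummarizedExperiment(
        assays = list(fingerprints = t(values)),
        rowData = S4Vectors::DataFrame(kind = descriptorKind,
                                       row.names = descriptorIds),
        colData = cd)
    metadata(se)$classNames <- classNames
    metadata(se)$scheme <- scheme
    new("FingerprintSet", se)
}

## coerce labels of any accepted form to 1-based integer indices
.labelIndices <- function(labels, classNames) {
    if (is.factor(labels)) labels <- as.character(labels)
    if (is.character(labels)) {
        idx <- match(labels, classNames)
        if (anyNA(idx))
            stop("unknown class label(s): ",
                 paste(unique(labels[is.na(idx)]), collapse = ", "))
        return(as.integer(idx))
    }
    as.integer(labels)
}

#' Canonical class orderings
#'
#' Weakest-to-strongest activity orderings used throughout: ties in any vote
#' or leaf labelling resolve toward the later (stronger) class.
#' @return character vector of ordered class names.
#' @export
binaryClasses <- function() c("Inactive", "Active")

#' @rdname binaryClasses
#' @export
multiclass5Classes <- function()
    c("Inactive", "Very Weak", "Weak", "Moderate", "Strong")

#' Accessors for FingerprintSet
#'
#' \code{fingerprintMatrix} returns the substances x descriptors numeric
#' matrix (the user-facing orientation); \code{descriptorKind},
#' \code{substanceIds} and \code{descriptorIds} return the per-descriptor
#' kind flags and identifiers; \code{activityLabels} returns labels as a
#' factor ordered weakest to strongest (or \code{NULL});
#' \code{labelIndices} the 1-based integer codes; \code{sourceCounts} the
#' per-substance source counts (or \code{NULL}); \code{classNames} and
#' \code{activityScheme} the class ordering and scheme.
#'
#' @param x a \code{FingerprintSet}.
#' @name fingerprintMatrix
#' @aliases descriptorKind substanceIds descriptorIds activityLabels
#'   labelIndices sourceCounts classNames activityScheme
NULL

#' @rdname fingerprintMatrix
#' @export
fingerprintMatrix <- function(x) t(assay(x, "fingerprints"))

#' @rdname fingerprintMatrix
#' @export
descriptorKind <- function(x) as.character(rowData(x)$kind)

#' @rdname fingerprintMatrix
#' @export
substanceIds <- function(x) colnames(x)

#' @rdname fingerprintMatrix
#' @export
descriptorIds <- function(x) rownames(x)

#' @rdname fingerprintMatrix
#' @export
classNames <- function(x) {
    if (is(x, "FingerprintSet")) metadata(x)$classNames
    else if (is(x, "ConfusionMatrix")) x@classNames
    else x@classNames
}

#' @rdname fingerprintMatrix
#' @export
activityScheme <- function(x) metadata(x)$scheme

#' @rdname fingerprintMatrix
#' @export
labelIndices <- function(x) {
    lab <- colData(x)$label
    if (is.null(lab)) NULL else as.integer(lab)
}

#' @rdname fingerprintMatrix
#' @export
activityLabels <- function(x) {
    idx <- labelIndices(x)
    if (is.null(idx)) return(NULL)
    factor(classNames(x)[idx], levels = classNames(x), ordered = TRUE)
}

#' @rdname fingerprintMatrix
#' @export
sourceCounts <- function(x) {
    sc <- colData(x)$sourceCount
    if (is.null(sc)) NULL else as.integer(sc)
}

#' @describeIn FingerprintSet compact display of dimensions, kinds, scheme
#'   and class balance.
#' @param object a \code{FingerprintSet}.
#' @export
setMethod("show", "FingerprintSet", function(object) {
    kind <- descriptorKind(object)
    cat("FingerprintSet:", ncol(object), "substances x", nrow(object),
        "descriptors (", sum(kind == "binary"), "binary,",
        sum(kind == "continuous"), "continuous )\n")
    cat("scheme:", activityScheme(object), "| classes:",
        paste(classNames(object), collapse = " < "), "\n")
    lab <- activityLabels(object)
    if (!is.null(lab)) {
        tab <- table(lab)
        cat("labels:", paste(names(tab), as.integer(tab),
                             sep = "=", collapse = ", "), "\n")
    }
    if (!is.null(sourceCounts(object)))
        cat("source counts: present\n")
    invisible(NULL)
})

#' Read a fingerprint CSV trio into a FingerprintSet
#'
#' Reads the package's CSV dialect: a fingerprint file whose first column is
#' \code{substance_id} and whose remaining (header-named) columns are
#' descriptors, plus optional sidecar files of labels
#' (\code{substance_id,label}) and source counts
#' (\code{substance_id,n_sources}). Rows with missing descriptor values are
#' rejected by default; with \code{impute = TRUE} continuous descriptors are
#' imputed with their column median (computed on the rows being loaded) and
#' rows with missing binary bits are still rejected.
#'
#' @param file fingerprint CSV path.
#' @param labelsFile,sourcesFile optional sidecar CSV paths.
#' @param scheme,classNames as in [FingerprintSet()].
#' @param descriptorKind optional kind flags; inferred from the data when
#'   omitted (0/1-valued columns are binary).
#' @param impute impute missing continuous values with the column median
#'   instead of rejecting the row.
#' @return a \code{FingerprintSet}.
#' @export
readFingerprintCSV <- function(file, labelsFile = NULL, sourcesFile = NULL,
                               scheme = c("binary", "multiclass5"),
                               classNames = NULL, descriptorKind = NULL,
                               impute = FALSE) {
    scheme <- match.arg(scheme)
    df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1L] != "substance_id")
        stop("first column of ", file, " must be 'substance_id'")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (anyNA(m)) {
        if (impute) {
            isBin <- apply(m, 2L, function(v) all(v %in% c(0, 1, NA)))
            for (j in which(!isBin)) {
                nas <- is.na(m[, j])
                if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
            }
        }
        bad <- rowSums(is.na(m)) > 0
        if (any(bad)) {
            if (!impute)
                stop(sum(bad), " substance(s) have missing descriptor values ",
                     "(set impute = TRUE to median-impute continuous columns)")
            warning(sum(bad), " substance(s) dropped: missing binary bits")
            m <- m[!bad, , drop = FALSE]
            ids <- ids[!bad]
        }
    }
    labels <- NULL
    if (!is.null(labelsFile)) {
        ld <- utils::read.csv(labelsFile, stringsAsFactors = FALSE)
        labels <- ld[[2L]][match(ids, as.character(ld[[1L]]))]
        if (anyNA(labels)) stop("labels missing for some substances")
    }
    sources <- NULL
    if (!is.null(sourcesFile)) {
        sd <- utils::read.csv(sourcesFile, stringsAsFactors = FALSE)
        sources <- as.integer(sd[[2L]][match(ids, as.character(sd[[1L]]))])
        if (anyNA(sources)) stop("source counts missing for some substances")
    }
    FingerprintSet(m, descriptorKind = descriptorKind, labels = labels,
                   classNames = classNames, scheme = scheme,
                   sourceCounts = sources)
}

#' Write a FingerprintSet as the CSV trio
#'
#' Inverse of [readFingerprintCSV()]: writes \code{<prefix>_fingerprints.csv}
#' and, when present, \code{<prefix>_labels.csv} and
#' \code{<prefix>_sources.csv}.
#'
#' @param x a \code{FingerprintSet}.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeFingerprintCSV <- function(x, prefix) {
    fp <- file.path(paste0(prefix, "_fingerprints.csv"))
    df <- data.frame(substance_id = substanceIds(x),
                     fingerprintMatrix(x), check.names = FALSE)
    utils::write.csv(df, fp, row.names = FALSE)
    paths <- fp
    lab <- activityLabels(x)
    if (!is.null(lab)) {
        lp <- paste0(prefix, "_labels.csv")
        utils::write.csv(data.frame(substance_id = substanceIds(x),
                                    label = as.character(lab)),
                         lp, row.names = FALSE)
        paths <- c(paths, lp)
    }
    sc <- sourceCounts(x)
    if (!is.null(sc)) {
        sp <- paste0(prefix, "_sources.csv")
        utils::write.csv(data.frame(substance_id = substanceIds(x),
                                    n_sources = sc),
                         sp, row.names = FALSE)
        paths <- c(paths, sp)
    }
    invisible(paths)
}
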