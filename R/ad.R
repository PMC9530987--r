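#' n^(1/m) applicability-domain threshold
#'
#' The density-kNN applicability domain is parameterized by the expression
#' \eqn{n^{1/m}}, where \eqn{n} is the number of training points and
#' \eqn{m} a tuning exponent chosen to trade prediction quality against
#' coverage. In this package the value is used as a quantile index into
#' the sorted per-point admission radii (see [fitAD()]): larger \eqn{m}
#' selects a smaller index, hence a smaller radius cap and a tighter
#' domain.
#'
#' @param n number of training points (>= 1).
#' @param m positive exponent.
#' @return \code{n^(1/m)}.
#' @examples
#' adThreshold(10000, 2)  # 100
#' @export
adThreshold <- function(n, m) {
    if (n < 1) stop("n must be >= 1")
    if (m <= 0) stop("m must be positive")
    n^(1 / m)
}

## PCA retaining the smallest number of components whose cumulative
## explained-variance ratio reaches varTarget, with deterministic signs
## (largest-magnitude loading positive).
.fitPCA <- function(x, varTarget = 0.95) {
    if (varTarget <= 0 || varTarget > 1) stop("varTarget must be in (0, 1]")
    if (nrow(x) < 2L) stop("need >= 2 substances")
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    ratio <- pc$sdev^2 / sum(pc$sdev^2)
    nc <- which(cumsum(ratio) >= varTarget - 1e-12)[1L]
    if (is.na(nc)) nc <- length(ratio)
    rot <- pc$rotation[, seq_len(nc), drop = FALSE]
    for (j in seq_len(nc)) {
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) rot[, j] <- -rot[, j]
    }
    list(center = pc$center, rotation = rot,
         varExplained = cumsum(ratio)[nc],
         embedding = sweep(x, 2L, pc$center) %*% rot)
}

## Squared cross-distances between rows of a (q x c) and b (n x c).
.crossDist2 <- function(a, b) {
    an <- rowSums(a^2); bn <- rowSums(b^2)
    d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    d2
}

#' Fit a density-kNN applicability domain
#'
#' Embeds the (pruned) training fingerprints with PCA, keeping the
#' smallest number of components that explain at least \code{varTarget}
#' (default 95\%) of the variance, then gives every training point an
#' admission radius equal to its mean Euclidean distance to its \code{k}
#' nearest training neighbours. Radii are capped at a global reference:
#' the \code{ceiling(n^(1/m))}-th smallest per-point radius, so larger
#' \code{m} tightens the domain (at \code{m = 1} no radius is capped).
#' A query is in-domain when it lies within the capped radius of at least
#' one training point.
#'
#' @param fp training data: \code{FingerprintSet} or numeric substances x
#'   descriptors matrix, with constant descriptors already pruned.
#' @param k neighbour count (default 5; must be < n).
#' @param m threshold exponent.
#' @param varTarget PCA cumulative explained-variance target.
#' @return an [ADModel-class].
#' @export
fitAD <- function(fp, k = 5L, m = 3, varTarget = 0.95) {
    x <- if (is(fp, "FingerprintSet")) fingerprintMatrix(fp) else as.matrix(fp)
    if (is.null(colnames(x)))
        colnames(x) <- paste0("descriptor", seq_len(ncol(x)))
    n <- nrow(x)
    if (k >= n) stop("k must be smaller than the number of training points")
    pca <- .fitPCA(x, varTarget)
    d2 <- .crossDist2(pca$embedding, pca$embedding)
    diag(d2) <- Inf
    radii <- apply(d2, 1L, function(row)
        mean(sqrt(sort(row, partial = k)[seq_len(k)])))
    ad <- new("ADModel", center = pca$center, rotation = pca$rotation,
              varExplained = pca$varExplained,
              embedding = pca$embedding, k = as.integer(k),
              radii = radii, m = as.numeric(m),
              cap = 0, descriptorIds = colnames(x))
    setADm(ad, m)
}

#' @rdname fitAD
#' @param ad an \code{ADModel}.
#' @return \code{setADm}: the model with \code{m} and the derived radius
#'   cap updated (no refit needed).
#' @export
setADm <- function(ad, m) {
    n <- nrow(ad@embedding)
    t <- min(max(ceiling(adThreshold(n, m)), 1L), n)
    ad@m <- as.numeric(m)
    ad@cap <- sort(ad@radii)[t]
    ad
}

#' @rdname fitAD
#' @return \code{admissionRadii}: the capped per-point radii actually used
#'   by [inDomain()].
#' @export
admissionRadii <- function(ad) pmin(ad@radii, ad@cap)

#' @describeIn fitAD display AD summary.
#' @param object an \code{ADModel}.
#' @export
setMethod("show", "ADModel", function(object) {
    cat("ADModel (density-kNN on PCA embedding)\n")
    cat(" ", nrow(object@embedding), "training points,",
        ncol(object@rotation), "components (",
        sprintf("%.1f%%", 100 * object@varExplained), "variance )\n")
    cat("  k =", object@k, "| m =", object@m,
        "| radius cap =", signif(object@cap, 4), "\n")
    invisible(NULL)
})

#' Applicability-domain membership
#'
#' Projects queries (given in the original descriptor space the AD was
#' fitted on) into the stored PCA basis and flags each as in-domain when
#' its Euclidean distance to at least one training point does not exceed
#' that point's capped admission radius. Deterministic and independent of
#' query order; every training point is in-domain with respect to itself.
#'
#' @param ad an [ADModel-class].
#' @param query \code{FingerprintSet} or numeric matrix with the AD's
#'   descriptors.
#' @return logical vector, one flag per query substance.
#' @export
inDomain <- function(ad, query) {
    X <- .alignDescriptors(query, ad@descriptorIds)
    emb <- sweep(X, 2L, ad@center) %*% ad@rotation
    r2 <- admissionRadii(ad)^2
    d2 <- .crossDist2(emb, ad@embedding)
    as.logical(apply(sweep(d2, 2L, r2, "<="), 1L, any))
}

## Balanced accuracy over the observed classes actually present (used when
## an AD restriction removes a class entirely).
.safeBA <- function(observed, predicted, k) {
    ok <- vapply(seq_len(k), function(c) any(observed == c), TRUE)
    mean(vapply(which(ok), function(c)
        mean(predicted[observed == c] == c), 0))
}

#' Optimize the AD threshold exponent m
#'
#' Scans a grid of \code{m} values and, for each, evaluates the forest's
#' balanced accuracy restricted to in-domain substances and the resulting
#' coverage. The chosen \code{m} maximizes the in-domain BA subject to
#' coverage >= \code{covMin} (default 0.85, i.e. removing at most about
#' 15\% of the data); ties prefer higher coverage. If no grid value
#' satisfies the constraint, the BA-improving value with the highest
#' coverage is returned (or, failing that too, the highest-coverage value
#' overall).
#'
#' @param ad an [ADModel-class] (any starting \code{m}).
#' @param forest the [ConservativeForest-class] being domained.
#' @param data labelled evaluation \code{FingerprintSet} (typically the
#'   held-out test set).
#' @param mGrid candidate exponents.
#' @param covMin minimum acceptable coverage.
#' @return list with \code{m} (chosen), \code{ad} (model at the chosen
#'   \code{m}), and \code{metrics} (data.frame of m, inDomainBA,
#'   coverage, baselineBA).
#' @export
optimizeM <- function(ad, forest, data, mGrid = seq(1, 10, by = 0.5),
                      covMin = 0.85) {
    if (!length(mGrid)) stop("mGrid is empty")
    y <- labelIndices(data)
    k <- length(forest@classNames)
    pred <- predict(forest, data)
    baseBA <- .safeBA(y, pred, k)
    X <- .alignDescriptors(data, ad@descriptorIds)
    rows <- lapply(mGrid, function(m) {
        adm <- setADm(ad, m)
        flags <- inDomain(adm, X)
        cov <- mean(flags)
        ba <- if (any(flags)) .safeBA(y[flags], pred[flags], k) else NA_real_
        data.frame(m = m, inDomainBA = ba, coverage = cov,
                   baselineBA = baseBA)
    })
    metrics <- do.call(rbind, rows)
    feasible <- !is.na(metrics$inDomainBA) & metrics$coverage >= covMin
    if (any(feasible)) {
        sub <- metrics[feasible, ]
        best <- sub[order(-sub$inDomainBA, -sub$coverage), ][1L, ]
    } else {
        improving <- !is.na(metrics$inDomainBA) &
            metrics$inDomainBA > baseBA
        pool <- if (any(improving)) metrics[improving, ] else metrics
        best <- pool[order(-pool$coverage, -pool$inDomainBA), ][1L, ]
    }
    list(m = best$m, ad = setADm(ad, best$m), metrics = metrics)
}
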