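## Small deterministic fixtures shared across test files.

## A tiny labelled set with one perfectly separating bit, one noise bit and
## one continuous descriptor.
tinySeparableSet <- function(n = 40L, seed = 42L) {
    withr::with_seed(seed, {
        y <- rep(c(1L, 2L), length.out = n)
        sig <- as.integer(y == 2L)
        noise <- rbinom(n, 1L, 0.5)
        mw <- rnorm(n, mean = 100 + 20 * (y - 1L), sd = 5)
        m <- cbind(sig = sig, noise = noise, mw = mw)
        rownames(m) <- sprintf("t%03d", seq_len(n))
        FingerprintSet(m, descriptorKind = c("binary", "binary", "continuous"),
                       labels = y)
    })
}

## Random small instance for property tests: nBinary bits + nCont continuous
## descriptors, arbitrary labels over k classes.
randomInstance <- function(n, nBinary, nCont, k, seed) {
    withr::with_seed(seed, {
        m <- cbind(
            matrix(rbinom(n * nBinary, 1L, runif(1, 0.2, 0.8)), n, nBinary),
            if (nCont > 0) matrix(rnorm(n * nCont), n, nCont))
        colnames(m) <- paste0("d", seq_len(ncol(m)))
        y <- sample.int(k, n, replace = TRUE)
        while (length(unique(y)) < 2L) y <- sample.int(k, n, replace = TRUE)
        list(x = m, y = y,
             kind = c(rep("binary", nBinary), rep("continuous", nCont)))
    })
}

## Exhaustive best-split oracle: enumerates every (descriptor, threshold)
## candidate over the given feature set under the same tie rule (lowest
## feature index, then lowest threshold) and the same strict-improvement
## requirement as the learner. Independent of the learner's implementation.
bruteForceBestSplit <- function(idx, x, y, kind, bins, k, cost, fBeta = 1) {
    yv <- y[idx]
    cnts <- tabulate(yv, k)
    baseline <- ConservativeRF:::.scoreUnsplit(cost, cnts, fBeta)
    best <- NULL
    bestScore <- baseline
    for (j in seq_len(ncol(x))) {
        thresholds <- if (kind[j] == "binary") 0.5
                      else bins[[as.character(j)]]
        for (thr in thresholds) {
            mask <- x[idx, j] <= thr
            sc <- splitCost(cost, yv, mask, k, fBeta)
            if (sc > bestScore + 1e-12) {
                bestScore <- sc
                best <- list(feature = j, threshold = thr, score = sc)
            }
        }
    }
    best
}
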