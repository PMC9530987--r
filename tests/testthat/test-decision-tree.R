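test_that("equal-width binning reproduces the molar-mass worked example", {
    b <- computeBins(c(50, 250), nBins = 20L)
    expect_equal(b, seq(60, 240, by = 10))
    expect_length(b, 19L)
    expect_equal(computeBins(c(0, 1), nBins = 2L), 0.5)
    expect_identical(computeBins(rep(3.2, 10)), numeric(0))
    full <- computeBins(runif(100, 50, 250), nBins = 20L)
    expect_true(all(diff(full) > 0))
    expect_true(all(full > min(50) & full < 250))
})

test_that("split scores match hand-evaluated Gini values", {
    # pure children: weighted impurity 0, oriented score 0
    y <- c(1L, 1L, 2L, 2L)
    expect_equal(splitCost("gini", y, c(TRUE, TRUE, FALSE, FALSE), k = 2L), 0)
    # unsplit [5 A, 5 B] has Gini 0.5; node [3, 1] has Gini 0.375
    expect_equal(ConservativeRF:::.scoreUnsplit("gini", c(5L, 5L)), -0.5)
    expect_equal(ConservativeRF:::.scoreUnsplit("gini", c(3L, 1L)), -0.375)
    # empty child is rejected
    expect_identical(splitCost("gini", y, rep(TRUE, 4), k = 2L), -Inf)
})

test_that("best split finds a perfect separator and respects the tie rule", {
    x <- cbind(d1 = c(0, 0, 0, 1, 1, 1), d2 = c(0, 1, 0, 1, 0, 1))
    y <- c(1L, 1L, 1L, 2L, 2L, 2L)
    cfg <- treeConfig("gini", nFeatureSubset = 2L)
    sp <- withr::with_seed(1, bestSplit(1:6, x, y, kind = rep("binary", 2),
                                        bins = list(), k = 2L, config = cfg))
    expect_identical(sp$feature, 1L)
    # identical columns tie exactly: the lower index must win
    x2 <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1))
    sp2 <- withr::with_seed(1, bestSplit(1:4, x2, c(1L, 1L, 2L, 2L),
                                         kind = rep("binary", 2),
                                         bins = list(), k = 2L, config = cfg))
    expect_identical(sp2$feature, 1L)
})

test_that("best split agrees with an exhaustive oracle for all four costs", {
    cases <- expand.grid(seed = c(2L, 11L, 23L),
                         cost = c("gini", "ba", "mcc", "macro_f"),
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cases))) {
        cost <- cases$cost[i]
        inst <- randomInstance(n = 50L, nBinary = 6L, nCont = 4L, k = 3L,
                               seed = cases$seed[i])
        k <- 3L
        bins <- setNames(lapply(7:10, function(j)
            computeBins(inst$x[, j], 20L)), as.character(7:10))
        cfg <- treeConfig(cost, nFeatureSubset = 10L)
        got <- withr::with_seed(99, bestSplit(seq_len(50L), inst$x, inst$y,
                                              inst$kind, bins, k, cfg))
        want <- bruteForceBestSplit(seq_len(50L), inst$x, inst$y, inst$kind,
                                    bins, k, cost)
        if (is.null(want)) {
            expect_null(got)
        } else {
            expect_identical(got$feature, want$feature,
                             label = paste("feature for", cost, cases$seed[i]))
            expect_equal(got$threshold, want$threshold)
            expect_equal(got$score, want$score)
        }
    }
})

test_that("growing stops on purity and learns separable data at depth 1", {
    pure <- FingerprintSet(cbind(b = c(0, 1, 0, 1)), labels = rep(1L, 4),
                           classNames = binaryClasses())
    t0 <- growTree(pure, seed = 1)
    expect_identical(treeDepth(t0), 0L)
    expect_true(t0@root$leaf)

    fps <- tinySeparableSet(40)
    t1 <- growTree(fps, config = treeConfig("gini", nFeatureSubset = 3L),
                   seed = 2)
    expect_identical(treeDepth(t1), 1L)
    pred <- predict(t1, fps)
    expect_equal(balancedAccuracy(confusion(fps, pred)), 1)
})

test_that("depth-1 trees cannot solve two-bit exclusive-or", {
    withr::with_seed(31, {
        a <- rep(c(0L, 1L), each = 20L)
        b <- rep(c(0L, 1L), 20L)
        y <- ifelse(xor(a == 1L, b == 1L), 2L, 1L)
        x <- cbind(xa = a, xb = b)
        for (seed in 1:4) {
            t1 <- growTree(x, y, kind = rep("binary", 2),
                           classNames = binaryClasses(),
                           config = treeConfig("gini", maxDepth = 1L,
                                               nFeatureSubset = 2L),
                           seed = seed)
            ba <- balancedAccuracy(confusion(factor(y, 1:2), predict(t1, x)))
            expect_lte(ba, 0.75)
        }
    })
})

test_that("every internal node routes at least one sample to each child", {
    inst <- randomInstance(n = 60L, nBinary = 8L, nCont = 3L, k = 2L, seed = 7L)
    tr <- growTree(inst$x, inst$y, kind = inst$kind,
                   classNames = binaryClasses(),
                   config = treeConfig("gini", maxDepth = 6L), seed = 3)
    walk <- function(node) {
        if (node$leaf) return(invisible(NULL))
        expect_gt(sum(node$left$counts), 0)
        expect_gt(sum(node$right$counts), 0)
        expect_identical(node$counts, node$left$counts + node$right$counts)
        walk(node$left); walk(node$right)
    }
    walk(tr@root)
})

test_that("prediction is conservative at leaves and under depth caps", {
    fps <- tinySeparableSet(40)
    tr <- growTree(fps, config = treeConfig("gini", nFeatureSubset = 3L),
                   seed = 2)
    # depth cap 0: root conservative majority for every substance
    rootMaj <- ConservativeRF:::.conservativeMajority(tr@root$counts)
    expect_true(all(predict(tr, fps, depthCap = 0L) == rootMaj))
    # cap at or beyond depth: identical to uncapped
    expect_identical(predict(tr, fps, depthCap = 50L), predict(tr, fps))
    # tied leaf counts resolve to the stronger class
    expect_identical(ConservativeRF:::.conservativeMajority(c(3L, 3L)), 2L)
    expect_identical(ConservativeRF:::.conservativeMajority(c(0L, 2L, 2L, 0L)), 3L)
})

test_that("predictions ignore descriptors the tree never references", {
    fps <- tinySeparableSet(30)
    tr <- growTree(fps, config = treeConfig("gini", nFeatureSubset = 3L),
                   seed = 5)
    base <- predict(tr, fps)
    extra <- cbind(fingerprintMatrix(fps),
                   unused = seq_len(30))
    expect_identical(predict(tr, extra), base)
    expect_error(predict(tr, fingerprintMatrix(fps)[, 1:2]), "missing")
})

test_that("training accuracy is non-decreasing in the depth cap", {
    inst <- randomInstance(n = 80L, nBinary = 10L, nCont = 2L, k = 2L,
                           seed = 19L)
    tr <- growTree(inst$x, inst$y, kind = inst$kind,
                   classNames = binaryClasses(),
                   config = treeConfig("gini", maxDepth = 8L,
                                       nFeatureSubset = 12L), seed = 4)
    acc <- vapply(0:treeDepth(tr), function(cap)
        mean(predict(tr, inst$x, depthCap = cap) == inst$y), 0)
    expect_true(all(diff(acc) >= -1e-12))
})

test_that("trees round-trip bit-exactly through JSON", {
    fps <- tinySeparableSet(40)
    tr <- growTree(fps, config = treeConfig("mcc", maxDepth = 4L), seed = 8)
    js <- treeToJSON(tr)
    back <- treeFromJSON(js)
    expect_identical(treeToJSON(back), js)
    expect_identical(predict(back, fps), predict(tr, fps))
    expect_identical(back@bins, tr@bins)
    expect_identical(back@config, tr@config)
})
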