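## A 2-substance-feature world where one deep tree memorizes the training
## data perfectly while the test labels are constructed to give a known
## test-set balanced accuracy.
.perfectTrainHalfTest <- function() {
    xTr <- cbind(sig = rep(c(0, 1), each = 10))
    rownames(xTr) <- sprintf("tr%02d", 1:20)
    yTr <- rep(c(1L, 2L), each = 10)
    # all test points sit on the x = 0 leaf; half are labelled Active, so
    # recall(Inactive) = 1 and recall(Active) = 0: test BA is exactly 0.5
    xTe <- cbind(sig = rep(0, 10))
    rownames(xTe) <- sprintf("te%02d", 1:10)
    yTe <- rep(c(1L, 2L), each = 5)
    forest <- trainForest(xTr, yTr, kind = "binary",
                          classNames = binaryClasses(), nTrees = 1L,
                          config = treeConfig("gini", nFeatureSubset = 1L),
                          trainFractionPerTree = 0.99, seed = 1)
    list(forest = forest, xTr = xTr, yTr = yTr, xTe = xTe, yTe = yTe)
}

test_that("fitness follows the mean-BA-minus-gap formula", {
    w <- .perfectTrainHalfTest()
    ident <- identityChromosome(w$forest)
    # train BA 1, test BA 0.5, lambda 0.5: F = 0.75 - 0.25 = 0.5
    expect_equal(chromosomeFitness(w$forest, ident, w$xTr, w$xTe,
                                   trainY = w$yTr, testY = w$yTe,
                                   lambda = 0.5), 0.5)
    # lambda 0 recovers the plain mean
    expect_equal(chromosomeFitness(w$forest, ident, w$xTr, w$xTe,
                                   trainY = w$yTr, testY = w$yTe,
                                   lambda = 0), 0.75)
    # perfect on both sides scores exactly 1
    expect_equal(chromosomeFitness(w$forest, ident, w$xTr, w$xTr,
                                   trainY = w$yTr, testY = w$yTr,
                                   lambda = 0.5), 1)
    # pure function: identical chromosomes, identical fitness
    expect_identical(
        chromosomeFitness(w$forest, ident, w$xTr, w$xTe,
                          trainY = w$yTr, testY = w$yTe),
        chromosomeFitness(w$forest, ident, w$xTr, w$xTe,
                          trainY = w$yTr, testY = w$yTe))
    allOff <- list(enabled = FALSE, depthCap = 0L)
    expect_identical(chromosomeFitness(w$forest, allOff, w$xTr, w$xTe,
                                       trainY = w$yTr, testY = w$yTe), -Inf)
})

test_that("applying a chromosome rewires prediction without touching trees", {
    fps <- tinySeparableSet(60)
    f <- trainForest(fps, nTrees = 3L, config = treeConfig("gini"), seed = 6)
    ident <- identityChromosome(f)
    expect_identical(predict(applyChromosome(f, ident), fps), predict(f, fps))
    solo <- list(enabled = c(TRUE, FALSE, FALSE),
                 depthCap = ident$depthCap)
    expect_identical(predict(applyChromosome(f, solo), fps),
                     predict(forestTrees(f)[[1]], fps))
    capped <- list(enabled = rep(TRUE, 3), depthCap = rep(0L, 3))
    rootVotes <- vapply(forestTrees(f), function(t)
        ConservativeRF:::.conservativeMajority(t@root$counts), 0L)
    tally <- tabulate(rootVotes, 2L)
    expect_true(all(predict(applyChromosome(f, capped), fps) ==
                    conservativeVote(tally)))
    expect_error(applyChromosome(f, list(enabled = rep(FALSE, 3),
                                         depthCap = rep(0L, 3))),
                 "disables")
})

test_that("evolution is elitist, seeded and never below the identity forest", {
    fps <- generateFingerprintData(generatorSpec(
        nSubstances = 240L, nBinary = 24L, nContinuous = 3L,
        classPriors = c(0.7, 0.3), nInformative = 6L, bitEffect = 0.3,
        nDuplicate = 0L, nConstant = 0L, seed = 9L))
    sp <- stratifiedSplit(fps, 0.75, seed = 2)
    tr <- fps[, trainIndices(sp)]; te <- fps[, testIndices(sp)]
    f <- trainForest(tr, nTrees = 7L,
                     config = treeConfig("gini", maxDepth = 6L), seed = 3)
    cfg <- gaConfig(populationSize = 10L, nGenerations = 8L, seed = 21L)
    ga <- evolveForest(f, tr, te, cfg)
    expect_true(all(diff(ga$history) >= 0))
    expect_gte(ga$fitness, ga$identityFitness)
    ga2 <- evolveForest(f, tr, te, cfg)
    expect_identical(ga$best, ga2$best)
    expect_identical(ga$history, ga2$history)
    zero <- evolveForest(f, tr, te, gaConfig(populationSize = 4L,
                                             nGenerations = 0L))
    expect_identical(zero$best, identityChromosome(f))
})

test_that("the GA reaches the exhaustive optimum on a small forest", {
    fps <- generateFingerprintData(generatorSpec(
        nSubstances = 160L, nBinary = 12L, nContinuous = 2L,
        classPriors = c(0.65, 0.35), nInformative = 4L, bitEffect = 0.35,
        nDuplicate = 0L, nConstant = 0L, seed = 14L))
    sp <- stratifiedSplit(fps, 0.75, seed = 4)
    tr <- fps[, trainIndices(sp)]; te <- fps[, testIndices(sp)]
    f <- trainForest(tr, nTrees = 3L,
                     config = treeConfig("gini", maxDepth = 2L), seed = 8)
    ev <- ConservativeRF:::.makeFitnessEvaluator(
        f, fingerprintMatrix(tr), labelIndices(tr),
        fingerprintMatrix(te), labelIndices(te), lambda = 0.5)
    depths <- vapply(forestTrees(f), treeDepth, 0L)
    genes <- lapply(depths, function(d)
        c(list(NULL), lapply(0:d, identity)))   # NULL = disabled
    combos <- expand.grid(g1 = genes[[1]], g2 = genes[[2]], g3 = genes[[3]])
    bestExhaustive <- -Inf
    for (i in seq_len(nrow(combos))) {
        caps <- c(combos$g1[[i]], combos$g2[[i]], combos$g3[[i]])
        enabled <- !vapply(list(combos$g1[[i]], combos$g2[[i]],
                                combos$g3[[i]]), is.null, TRUE)
        if (!any(enabled)) next
        full <- integer(3); full[enabled] <- caps
        fit <- ev(list(enabled = enabled, depthCap = full))
        bestExhaustive <- max(bestExhaustive, fit)
    }
    ga <- evolveForest(f, tr, te,
                       gaConfig(populationSize = 20L, nGenerations = 25L,
                                mutationRate = 0.15, seed = 5L))
    expect_equal(ga$fitness, bestExhaustive, tolerance = 1e-12)
})
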