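test_that("the n^(1/m) threshold evaluates and validates correctly", {
    expect_equal(adThreshold(10000, 2), 100)
    expect_equal(adThreshold(1, 0.37), 1)
    expect_equal(adThreshold(1e6, 1e9), 1, tolerance = 1e-6)
    expect_error(adThreshold(100, 0), "positive")
    expect_error(adThreshold(0, 2), "n must be")
})

test_that("PCA retains the fewest components reaching the variance target", {
    # build a matrix with exactly known variance ratios via an orthonormal,
    # column-centred basis scaled by the target singular values
    withr::with_seed(5, {
        A <- matrix(rnorm(20 * 4), 20, 4)
        A <- sweep(A, 2, colMeans(A))
        Q <- qr.Q(qr(A))
        X <- Q %*% diag(sqrt(c(0.6, 0.3, 0.05, 0.05)))
        colnames(X) <- paste0("d", 1:4)
    })
    fit <- ConservativeRF:::.fitPCA(X, varTarget = 0.95)
    expect_identical(ncol(fit$rotation), 3L)
    expect_equal(fit$varExplained, 0.95, tolerance = 1e-8)
    # single descriptor: one component explaining everything
    one <- matrix(rnorm(10), dimnames = list(NULL, "d1"))
    f1 <- ConservativeRF:::.fitPCA(one, 0.95)
    expect_identical(ncol(f1$rotation), 1L)
    expect_equal(f1$varExplained, 1)
    expect_error(ConservativeRF:::.fitPCA(X, 1.2), "varTarget")
    # embedding variances must match a direct eigendecomposition oracle
    ev <- eigen(cov(X), symmetric = TRUE)$values
    embVar <- apply(ConservativeRF:::.fitPCA(X, 1)$embedding, 2, var)
    expect_equal(unname(embVar), ev[seq_along(embVar)], tolerance = 1e-8)
})

test_that("distances in the embedding agree with a brute-force oracle", {
    withr::with_seed(3, {
        x <- matrix(rnorm(12 * 5), 12, 5,
                    dimnames = list(NULL, paste0("d", 1:5)))
    })
    ad <- fitAD(x, k = 3L, m = 1)
    d2 <- ConservativeRF:::.crossDist2(ad@embedding, ad@embedding)
    oracle <- as.matrix(dist(ad@embedding))^2
    expect_equal(d2, oracle, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("training points are in-domain; far queries are not", {
    withr::with_seed(7, {
        x <- matrix(rnorm(40 * 6), 40, 6,
                    dimnames = list(NULL, paste0("d", 1:6)))
    })
    ad <- fitAD(x, k = 5L, m = 1)
    expect_true(all(inDomain(ad, x)))
    far <- matrix(1e6, 2, 6, dimnames = list(NULL, paste0("d", 1:6)))
    expect_identical(inDomain(ad, far), c(FALSE, FALSE))
    # duplicate of a training substance is always inside
    expect_true(inDomain(ad, x[5, , drop = FALSE]))
    # query order does not matter
    q <- rbind(far, x[1:3, ])
    expect_identical(inDomain(ad, q), inDomain(ad, q[5:1, ])[5:1])
})

test_that("a mid-gap query between well-separated clusters is out of domain", {
    withr::with_seed(11, {
        c1 <- matrix(rnorm(30 * 3, mean = 0, sd = 0.5), 30, 3)
        c2 <- matrix(rnorm(30 * 3, mean = 10, sd = 0.5), 30, 3)
        x <- rbind(c1, c2)
        colnames(x) <- paste0("d", 1:3)
    })
    ad <- fitAD(x, k = 4L, m = 1)
    mid <- matrix(5, 1, 3, dimnames = list(NULL, paste0("d", 1:3)))
    expect_false(inDomain(ad, mid))
    members <- x[c(3, 33), ]
    expect_true(all(inDomain(ad, members)))
})

test_that("coverage shrinks monotonically as the domain tightens", {
    withr::with_seed(13, {
        x <- matrix(rnorm(80 * 5), 80, 5,
                    dimnames = list(NULL, paste0("d", 1:5)))
        q <- matrix(rnorm(60 * 5), 60, 5,
                    dimnames = list(NULL, paste0("d", 1:5)))
    })
    ad <- fitAD(x, k = 5L, m = 1)
    # larger m gives a smaller radius cap, hence non-increasing coverage
    covs <- vapply(c(1, 2, 3, 5, 8), function(m)
        coverage(inDomain(setADm(ad, m), q)), 0)
    expect_true(all(diff(covs) <= 1e-12))
    # direct radius shrinkage: scaling all radii down cannot raise coverage
    shrunk <- ad
    shrunk@radii <- ad@radii * 0.5
    shrunk@cap <- ad@cap * 0.5
    expect_lte(coverage(inDomain(shrunk, q)), coverage(inDomain(ad, q)))
    # a distribution shift cannot increase coverage
    shifted <- sweep(q, 2, rep(5, 5), "+")
    expect_lte(coverage(inDomain(ad, shifted)), coverage(inDomain(ad, q)))
})

test_that("m optimization respects the coverage constraint semantics", {
    suite <- makeBenchmarkSuite(7)
    fps <- suite$contaminated
    sp <- stratifiedSplit(fps, 0.75, seed = 7)
    pr <- pruneFingerprints(fps[, trainIndices(sp)])
    tr <- pr$fp
    te <- applyKeepList(fps[, testIndices(sp)], pr$report$keep)
    f <- trainForest(tr, nTrees = 15L,
                     config = treeConfig("gini", maxDepth = 8L), seed = 7)
    ad <- fitAD(tr, k = 5L, m = 1)
    mo <- optimizeM(ad, f, te, mGrid = seq(1, 6, by = 0.5), covMin = 0.85)
    met <- mo$metrics
    feasible <- met[met$coverage >= 0.85 & !is.na(met$inDomainBA), ]
    if (nrow(feasible)) {
        expect_equal(max(feasible$inDomainBA),
                     met$inDomainBA[met$m == mo$m])
        expect_gte(met$coverage[met$m == mo$m], 0.85)
    }
    # singleton grid returns that m
    expect_equal(optimizeM(ad, f, te, mGrid = 2.5)$m, 2.5)
    expect_error(optimizeM(ad, f, te, mGrid = numeric(0)), "empty")
})

test_that("the tuned domain excludes contaminants and lifts in-domain accuracy", {
    suite <- makeBenchmarkSuite(7)
    fps <- suite$contaminated
    sp <- stratifiedSplit(fps, 0.75, seed = 7)
    pr <- pruneFingerprints(fps[, trainIndices(sp)])
    tr <- pr$fp
    te <- applyKeepList(fps[, testIndices(sp)], pr$report$keep)
    f <- trainForest(tr, nTrees = 21L,
                     config = treeConfig("gini", maxDepth = 8L), seed = 7)
    mo <- optimizeM(fitAD(tr, k = 5L, m = 1), f, te,
                    mGrid = seq(1, 10, by = 0.5))
    flags <- inDomain(mo$ad, te)
    contam <- SummarizedExperiment::colData(te)$contaminant
    # contaminants are excluded far more often than genuine substances
    expect_gt(mean(!flags[contam]), mean(!flags[!contam]) + 0.2)
    ev <- evaluateModel(f, te, mo$ad)
    expect_gt(ev$inDomain$ba, ev$all$ba)
})
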