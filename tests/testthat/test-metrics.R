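test_that("confusion tallies observed x predicted counts", {
    cm <- confusion(c(1L, 2L), c(1L, 2L), classNames = binaryClasses())
    expect_identical(unname(diag(counts(cm))), c(1L, 1L))
    cm2 <- confusion(c(2L, 2L), c(1L, 1L), classNames = binaryClasses())
    expect_identical(unname(counts(cm2)[2L, 1L]), 2L)
    expect_error(confusion(1:3, 1:2, classNames = multiclass5Classes()),
                 "equal length")
    withr::with_seed(8, {
        obs <- sample.int(3L, 10L, replace = TRUE)
        prd <- sample.int(3L, 10L, replace = TRUE)
        cm3 <- confusion(obs, prd, classNames = c("a", "b", "c"))
        expect_identical(unname(rowSums(counts(cm3))),
                         vapply(1:3, function(c) sum(obs == c), 0))
    })
})

test_that("balanced accuracy is the mean per-class recall", {
    cm <- confusion(rep(1:2, c(4, 6)), c(1, 1, 1, 2, rep(2, 5), 1),
                    classNames = binaryClasses())
    # recalls: 3/4 and 5/6 computed by hand
    expect_equal(balancedAccuracy(cm), (3 / 4 + 5 / 6) / 2)
    expect_equal(unname(perClassRecall(cm)), c(3 / 4, 5 / 6))
    diagonal <- confusion(1:5, 1:5, classNames = multiclass5Classes())
    expect_equal(balancedAccuracy(diagonal), 1)
    expect_error(balancedAccuracy(confusion(c(1L, 1L), c(1L, 2L),
                                            classNames = binaryClasses())),
                 "Active")
})

test_that("an always-one-class predictor scores 1/k for any imbalance", {
    for (k in 2:6) {
        withr::with_seed(k, {
            obs <- c(seq_len(k), sample.int(k, 40L, replace = TRUE,
                                            prob = c(0.9, rep(0.1 / (k - 1),
                                                              k - 1))))
            prd <- rep(1L, length(obs))
            cm <- confusion(obs, prd, classNames = paste0("c", seq_len(k)))
            expect_equal(balancedAccuracy(cm), 1 / k)
        })
    }
})

test_that("balanced accuracy is invariant under consistent class relabeling", {
    withr::with_seed(21, {
        obs <- sample.int(4L, 60L, replace = TRUE)
        prd <- sample.int(4L, 60L, replace = TRUE)
        obs[1:4] <- 1:4
        cm <- confusion(obs, prd, classNames = paste0("c", 1:4))
        perm <- sample(4L)
        cmP <- confusion(perm[obs], perm[prd],
                         classNames = paste0("c", 1:4)[order(perm)])
        expect_equal(balancedAccuracy(cm), balancedAccuracy(cmP))
    })
})

test_that("binary statistics follow their definitions and BA identity", {
    perfect <- confusion(rep(1:2, 5), rep(1:2, 5), classNames = binaryClasses())
    st <- binaryStats(perfect)
    expect_equal(unlist(st), c(sensitivity = 1, specificity = 1,
                               precision = 1, recall = 1))
    withr::with_seed(4, {
        obs <- rep(1:2, c(30, 10))
        prd <- sample.int(2L, 40L, replace = TRUE)
        cm <- confusion(obs, prd, classNames = binaryClasses())
        s <- binaryStats(cm)
        expect_equal(balancedAccuracy(cm),
                     (s$sensitivity + s$specificity) / 2)
    })
    nonePredActive <- confusion(c(1L, 2L), c(1L, 1L),
                                classNames = binaryClasses())
    expect_true(is.na(binaryStats(nonePredActive)$precision))
})

test_that("multi-class MCC reduces to the classical binary formula", {
    perfect <- confusion(rep(1:2, 5), rep(1:2, 5), classNames = binaryClasses())
    expect_equal(mcc(perfect), 1)
    inverted <- confusion(rep(1:2, 5), rep(2:1, 5), classNames = binaryClasses())
    expect_equal(mcc(inverted), -1)
    m <- matrix(c(4L, 1L, 2L, 3L), 2, 2, byrow = TRUE)
    tn <- 4; fp <- 1; fn <- 2; tp <- 3
    classical <- (tp * tn - fp * fn) /
        sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    expect_equal(mcc(m), classical)
    expect_warning(val <- mcc(matrix(c(5L, 0L, 0L, 0L), 2, 2)), "degenerate")
    expect_identical(val, 0)
})

test_that("macro F averages one-vs-rest F1 with undefined classes scoring 0", {
    perfect <- confusion(1:3, 1:3, classNames = c("a", "b", "c"))
    expect_equal(macroF(perfect), 1)
    # balanced two-class data, everything predicted class 1:
    # F1(class1) = 2*2/(2*2+0+2) = 2/3, F1(class2) = 0
    cm <- confusion(c(1L, 1L, 2L, 2L), rep(1L, 4), classNames = binaryClasses())
    expect_equal(macroF(cm), (2 / 3 + 0) / 2)
    # k = 2 macro F equals the mean of the classical per-class F1s
    withr::with_seed(13, {
        obs <- rep(1:2, c(12, 8))
        prd <- sample.int(2L, 20L, replace = TRUE)
        m <- counts(confusion(obs, prd, classNames = binaryClasses()))
        f1 <- function(tp, fp, fn) if (2 * tp + fp + fn == 0) 0
                                   else 2 * tp / (2 * tp + fp + fn)
        oracle <- mean(c(f1(m[1, 1], m[2, 1], m[1, 2]),
                         f1(m[2, 2], m[1, 2], m[2, 1])))
        expect_equal(macroF(m), oracle)
    })
})

test_that("coverage is the in-domain fraction", {
    expect_equal(coverage(rep(TRUE, 7)), 1)
    expect_equal(coverage(c(rep(TRUE, 885), rep(FALSE, 115))), 0.885)
    expect_error(coverage(logical(0)), "empty")
})
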