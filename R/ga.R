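#' Genetic-algorithm configuration
#'
#' Hyperparameters of the post-hoc forest optimizer. The fitness rewards
#' the mean of training and test balanced accuracy and penalizes their gap:
#' \eqn{F = (BA_{train} + BA_{test})/2 - \lambda |BA_{train} - BA_{test}|}.
#' \code{lambda = 0} recovers the plain mean. This scoring is this
#' package's documented default, designed to improve the BA of both the
#' training and the testing data while guarding against overfitting.
#'
#' @param populationSize chromosomes per generation (>= 2).
#' @param nGenerations generations to evolve; 0 returns the identity
#'   chromosome untouched.
#' @param crossoverRate probability a selected pair recombines (uniform
#'   per-gene crossover).
#' @param mutationRate per-gene probability of flipping the enabled flag,
#'   and independently of perturbing the depth cap by +/-1 (clipped).
#' @param elitismCount best chromosomes copied unchanged each generation
#'   (>= 1 so best fitness is non-decreasing).
#' @param tournamentSize tournament size for parent selection.
#' @param lambda overfit-penalty weight in the fitness.
#' @param seed integer seed.
#' @return named list of GA parameters.
#' @export
gaConfig <- function(populationSize = 50L, nGenerations = 100L,
                     crossoverRate = 0.8, mutationRate = 0.05,
                     elitismCount = 2L, tournamentSize = 3L,
                     lambda = 0.5, seed = 1L) {
    stopifnot(populationSize >= 2L, elitismCount >= 1L,
              elitismCount < populationSize, tournamentSize >= 1L,
              nGenerations >= 0L)
    list(populationSize = as.integer(populationSize),
         nGenerations = as.integer(nGenerations),
         crossoverRate = as.numeric(crossoverRate),
         mutationRate = as.numeric(mutationRate),
         elitismCount = as.integer(elitismCount),
         tournamentSize = as.integer(tournamentSize),
         lambda = as.numeric(lambda), seed = as.integer(seed))
}

#' Forest chromosomes
#'
#' A chromosome assigns every tree of a forest an enabled flag and a depth
#' cap in \code{[0, tree depth]}; the genetic algorithm searches this
#' space. \code{identityChromosome} is the do-nothing genome: all trees
#' enabled at full depth.
#'
#' @param forest a [ConservativeForest-class].
#' @return list with \code{enabled} (logical) and \code{depthCap}
#'   (integer) per tree.
#' @export
identityChromosome <- function(forest) {
    list(enabled = rep(TRUE, length(forest@trees)),
         depthCap = vapply(forest@trees, treeDepth, 0L))
}

#' Apply a chromosome to a forest
#'
#' Overwrites the forest's enabled flags and depth caps; the trees
#' themselves are untouched (caps act at prediction time). A chromosome
#' disabling every tree is an error.
#'
#' @param forest a [ConservativeForest-class].
#' @param chromosome a chromosome list (see [identityChromosome()]).
#' @return the modified \code{ConservativeForest}.
#' @export
applyChromosome <- function(forest, chromosome) {
    stopifnot(length(chromosome$enabled) == length(forest@trees),
              length(chromosome$depthCap) == length(forest@trees))
    if (!any(chromosome$enabled))
        stop("chromosome disables every tree")
    forest@enabled <- as.logical(chromosome$enabled)
    forest@depthCap <- as.integer(chromosome$depthCap)
    validObject(forest)
    forest
}

.asXY <- function(data, y = NULL) {
    if (is(data, "FingerprintSet")) {
        list(x = fingerprintMatrix(data), y = labelIndices(data))
    } else list(x = as.matrix(data), y = as.integer(y))
}

## Fast chromosome evaluator. Precomputes every tree's per-depth
## predictions on the train and test matrices once; evaluating a
## chromosome is then a tally over enabled trees at their caps.
.makeFitnessEvaluator <- function(forest, trainX, trainY, testX, testY,
                                  lambda) {
    k <- length(forest@classNames)
    trees <- forest@trees
    trainX <- .alignDescriptors(trainX, forest@descriptorIds)
    testX <- .alignDescriptors(testX, forest@descriptorIds)
    Ptrain <- lapply(trees, function(tr) .treePathPredictions(tr, trainX))
    Ptest <- lapply(trees, function(tr) .treePathPredictions(tr, testX))
    trainIdx <- split(seq_along(trainY), factor(trainY, levels = seq_len(k)))
    testIdx <- split(seq_along(testY), factor(testY, levels = seq_len(k)))
    if (any(!lengths(trainIdx)) || any(!lengths(testIdx)))
        stop("train and test must each contain every class")
    ba <- function(pred, idxList) {
        mean(vapply(seq_len(k), function(c)
            mean(pred[idxList[[c]]] == c), 0))
    }
    voteOn <- function(P, n, enabled, caps) {
        tally <- matrix(0L, n, k)
        for (t in which(enabled)) {
            cap <- min(caps[t], ncol(P[[t]]) - 1L)
            v <- P[[t]][, cap + 1L]
            tally[cbind(seq_len(n), v)] <- tally[cbind(seq_len(n), v)] + 1L
        }
        max.col(tally, ties.method = "last")
    }
    function(chrom) {
        if (!any(chrom$enabled)) return(-Inf)
        baTr <- ba(voteOn(Ptrain, length(trainY), chrom$enabled,
                          chrom$depthCap), trainIdx)
        baTe <- ba(voteOn(Ptest, length(testY), chrom$enabled,
                          chrom$depthCap), testIdx)
        (baTr + baTe) / 2 - lambda * abs(baTr - baTe)
    }
}

#' Chromosome fitness
#'
#' Evaluates the GA fitness of one chromosome:
#' \eqn{F = (BA_{train} + BA_{test})/2 - \lambda |BA_{train} - BA_{test}|},
#' with balanced accuracies computed from the conservative forest
#' predictions under the chromosome. A chromosome disabling every tree has
#' fitness \code{-Inf}.
#'
#' @param forest a [ConservativeForest-class].
#' @param chromosome a chromosome list.
#' @param train,test labelled \code{FingerprintSet}s (or matrices with
#'   \code{trainY}/\code{testY}).
#' @param trainY,testY integer labels when matrices are supplied.
#' @param lambda overfit-penalty weight.
#' @return the scalar fitness.
#' @export
chromosomeFitness <- function(forest, chromosome, train, test,
                              trainY = NULL, testY = NULL, lambda = 0.5) {
    tr <- .asXY(train, trainY); te <- .asXY(test, testY)
    ev <- .makeFitnessEvaluator(forest, tr$x, tr$y, te$x, te$y, lambda)
    ev(chromosome)
}

#' Optimize a forest with a genetic algorithm
#'
#' Post-hoc optimizes a trained forest by independently capping each
#' tree's depth and switching trees off. The initial population seeds the
#' identity chromosome (all trees enabled, uncapped) alongside random
#' variants, so the optimized forest can never score below the unoptimized
#' one; selection is by tournament, recombination is uniform per-gene
#' crossover, mutation flips enabled flags and nudges depth caps by one,
#' and elitism preserves the best chromosomes, making the best fitness
#' non-decreasing across generations.
#'
#' @param forest a trained [ConservativeForest-class].
#' @param train,test labelled \code{FingerprintSet}s (or matrices with
#'   \code{trainY}/\code{testY}) -- the 75/25 split the forest was built
#'   from.
#' @param config a [gaConfig()] list.
#' @param trainY,testY integer labels when matrices are supplied.
#' @return list with \code{best} (chromosome), \code{fitness} (its
#'   fitness), \code{history} (per-generation best-ever fitness) and
#'   \code{identityFitness}.
#' @export
evolveForest <- function(forest, train, test, config = gaConfig(),
                         trainY = NULL, testY = NULL) {
    tr <- .asXY(train, trainY); te <- .asXY(test, testY)
    evalFit <- .makeFitnessEvaluator(forest, tr$x, tr$y, te$x, te$y,
                                     config$lambda)
    depths <- vapply(forest@trees, treeDepth, 0L)
    nT <- length(depths)
    identity <- identityChromosome(forest)
    idFit <- evalFit(identity)
    if (config$nGenerations == 0L)
        return(list(best = identity, fitness = idFit,
                    history = numeric(0), identityFitness = idFit))
    .withSeed(config$seed, {
        randomChrom <- function() {
            en <- stats::runif(nT) < 0.8
            if (!any(en)) en[sample.int(nT, 1L)] <- TRUE
            caps <- vapply(depths, function(d)
                sample.int(d + 1L, 1L) - 1L, 0L)
            list(enabled = en, depthCap = caps)
        }
        pop <- c(list(identity),
                 replicate(config$populationSize - 1L, randomChrom(),
                           simplify = FALSE))
        fits <- vapply(pop, evalFit, 0)
        bestIdx <- which.max(fits)
        best <- pop[[bestIdx]]; bestFit <- fits[bestIdx]
        history <- numeric(config$nGenerations)
        tourn <- function() {
            cand <- sample.int(config$populationSize,
                               min(config$tournamentSize,
                                   config$populationSize))
            cand[which.max(fits[cand])]
        }
        mutate <- function(ch) {
            flip <- stats::runif(nT) < config$mutationRate
            ch$enabled <- xor(ch$enabled, flip)
            if (!any(ch$enabled))
                ch$enabled[sample.int(nT, 1L)] <- TRUE
            nudge <- stats::runif(nT) < config$mutationRate
            if (any(nudge)) {
                delta <- sample(c(-1L, 1L), sum(nudge), replace = TRUE)
                ch$depthCap[nudge] <- pmin(pmax(ch$depthCap[nudge] + delta,
                                                0L), depths[nudge])
            }
            ch
        }
        for (g in seq_len(config$nGenerations)) {
            ord <- order(fits, decreasing = TRUE)
            nextPop <- pop[ord[seq_len(config$elitismCount)]]
            while (length(nextPop) < config$populationSize) {
                p1 <- pop[[tourn()]]; p2 <- pop[[tourn()]]
                if (stats::runif(1) < config$crossoverRate) {
                    mask <- stats::runif(nT) < 0.5
                    child <- list(
                        enabled = ifelse(mask, p1$enabled, p2$enabled),
                        depthCap = ifelse(mask, p1$depthCap, p2$depthCap))
                } else child <- p1
                child$depthCap <- as.integer(child$depthCap)
                nextPop[[length(nextPop) + 1L]] <- mutate(child)
            }
            pop <- nextPop
            fits <- vapply(pop, evalFit, 0)
            gi <- which.max(fits)
            if (fits[gi] > bestFit) {
                bestFit <- fits[gi]; best <- pop[[gi]]
            }
            history[g] <- bestFit
        }
        list(best = best, fitness = bestFit, history = history,
             identityFitness = idFit)
    })
}
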