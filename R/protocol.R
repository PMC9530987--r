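#' Full-protocol run configuration
#'
#' Bundles every tunable of the training protocol with its standard
#' default: deduplicate, optionally filter by minimum source count, split
#' 75/25 stratified, prune fingerprints on the training data (zero
#' variance, then |r| > 0.98 collinearity), train one 101-tree forest per
#' requested cost function, optimize each with the genetic algorithm,
#' keep the single best by GA fitness, fit the density-kNN applicability
#' domain (PCA at 95\% variance, k = 5) on the training data and tune its
#' exponent m, then evaluate. Round-trips losslessly through JSON via
#' [writeRunConfig()] / [readRunConfig()].
#'
#' @param nTrees trees per forest.
#' @param costs cost functions to train candidate forests with.
#' @param splitFraction training fraction of the global split.
#' @param trainFractionPerTree per-tree subsample fraction.
#' @param rMax collinearity pruning threshold.
#' @param absoluteCorrelation prune on |r| rather than signed r.
#' @param varTarget PCA explained-variance target for the AD.
#' @param maxDepth,nFeatureSubset,minNodeSize,nBins,fBeta tree parameters
#'   (see [treeConfig()]).
#' @param ga a [gaConfig()] list.
#' @param adK neighbour count of the applicability domain.
#' @param mGrid,covMin AD threshold-exponent grid and coverage floor (see
#'   [optimizeM()]).
#' @param minSources drop substances with fewer sources (\code{NULL} to
#'   skip; needs source counts in the data).
#' @param dedup remove duplicated substance identifiers first, resolving
#'   label conflicts to the strongest label.
#' @param seed master seed for the whole protocol.
#' @return a run-config list.
#' @export
runConfig <- function(nTrees = 101L,
                      costs = c("gini", "ba", "mcc", "macro_f"),
                      splitFraction = 0.75, trainFractionPerTree = 0.75,
                      rMax = 0.98, absoluteCorrelation = TRUE,
                      varTarget = 0.95, maxDepth = 20L,
                      nFeatureSubset = NULL, minNodeSize = 2L,
                      nBins = 20L, fBeta = 1, ga = gaConfig(),
                      adK = 5L, mGrid = seq(1, 10, by = 0.5),
                      covMin = 0.85, minSources = NULL, dedup = TRUE,
                      seed = 1L) {
    costs <- match.arg(costs, c("gini", "ba", "mcc", "macro_f"),
                       several.ok = TRUE)
    list(nTrees = as.integer(nTrees), costs = costs,
         splitFraction = as.numeric(splitFraction),
         trainFractionPerTree = as.numeric(trainFractionPerTree),
         rMax = as.numeric(rMax),
         absoluteCorrelation = isTRUE(absoluteCorrelation),
         varTarget = as.numeric(varTarget),
         maxDepth = as.integer(maxDepth),
         nFeatureSubset = if (is.null(nFeatureSubset)) NULL
                          else as.integer(nFeatureSubset),
         minNodeSize = as.integer(minNodeSize), nBins = as.integer(nBins),
         fBeta = as.numeric(fBeta), ga = ga, adK = as.integer(adK),
         mGrid = as.numeric(mGrid), covMin = as.numeric(covMin),
         minSources = if (is.null(minSources)) NULL
                      else as.integer(minSources),
         dedup = isTRUE(dedup), seed = as.integer(seed))
}

#' @rdname runConfig
#' @param config a run-config list.
#' @param path JSON file path.
#' @export
writeRunConfig <- function(config, path) {
    cfg <- config
    cfg$ga$seed <- as.integer(cfg$ga$seed)
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    l <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    ga <- do.call(gaConfig, l$ga)
    l$ga <- NULL
    l$costs <- as.character(l$costs)
    do.call(runConfig, c(l, list(ga = ga)))
}

#' Evaluate a forest (and optional applicability domain) on labelled data
#'
#' Computes the full metric block the screening context cares about --
#' confusion matrix, balanced accuracy, per-class recall, and for binary
#' schemes sensitivity/specificity/precision/recall -- twice: on all
#' substances and restricted to in-domain substances, plus the coverage.
#' With \code{ad = NULL} the two blocks coincide and coverage is 1.
#'
#' @param forest a [ConservativeForest-class].
#' @param data a labelled \code{FingerprintSet}.
#' @param ad an [ADModel-class] or \code{NULL}.
#' @return list with \code{all} and \code{inDomain} metric blocks (each a
#'   list with \code{confusion}, \code{ba}, \code{recall}, and binary
#'   stats when applicable), \code{coverage}, and the prediction vectors.
#' @export
evaluateModel <- function(forest, data, ad = NULL) {
    y <- labelIndices(data)
    if (is.null(y)) stop("evaluation data has no labels")
    pred <- predict(forest, data)
    flags <- if (is.null(ad)) rep(TRUE, length(y)) else inDomain(ad, data)
    block <- function(obs, prd) {
        cm <- confusion(obs, prd, classNames = forest@classNames)
        k <- length(forest@classNames)
        out <- list(confusion = cm,
                    ba = .safeBA(obs, prd, k),
                    perClassRecall = tryCatch(perClassRecall(cm),
                                              error = function(e) NULL))
        if (k == 2L) out <- c(out, binaryStats(cm))
        out
    }
    list(all = block(y, pred),
         inDomain = block(y[flags], pred[flags]),
         coverage = mean(flags),
         predicted = pred, inDomainFlags = flags)
}

## Flatten an evaluation into one metrics table (written as CSV).
.metricsTable <- function(ev, classNames) {
    row <- function(scope, b) {
        data.frame(scope = scope,
                   ba = b$ba,
                   sensitivity = if (!is.null(b$sensitivity)) b$sensitivity else NA,
                   specificity = if (!is.null(b$specificity)) b$specificity else NA,
                   precision = if (!is.null(b$precision)) b$precision else NA,
                   recall = if (!is.null(b$recall) && length(b$recall) == 1L)
                       b$recall else NA,
                   coverage = ev$coverage)
    }
    rbind(row("all", ev$all), row("in_domain", ev$inDomain))
}

.adToList <- function(ad) {
    list(center = ad@center, rotation = ad@rotation,
         varExplained = ad@varExplained, embedding = ad@embedding,
         k = ad@k, radii = ad@radii, m = ad@m, cap = ad@cap,
         descriptorIds = ad@descriptorIds)
}

.adFromList <- function(l) {
    rot <- do.call(rbind, lapply(l$rotation, function(r) as.numeric(unlist(r))))
    emb <- do.call(rbind, lapply(l$embedding, function(r) as.numeric(unlist(r))))
    rownames(rot) <- as.character(unlist(l$descriptorIds))
    new("ADModel", center = stats::setNames(as.numeric(unlist(l$center)),
                                            as.character(unlist(l$descriptorIds))),
        rotation = rot, varExplained = as.numeric(l$varExplained),
        embedding = emb, k = as.integer(l$k),
        radii = as.numeric(unlist(l$radii)), m = as.numeric(l$m),
        cap = as.numeric(l$cap),
        descriptorIds = as.character(unlist(l$descriptorIds)))
}

#' Run the full training protocol
#'
#' Executes the end-to-end pipeline on a labelled \code{FingerprintSet}:
#' deduplication, optional minimum-source filtering, stratified 75/25
#' split, fingerprint pruning fit on the training data, one forest per
#' requested cost function, genetic optimization of each, selection of
#' the single best candidate by GA fitness, applicability-domain fitting
#' and m-tuning, and evaluation on the held-out test set. When
#' \code{outDir} is given, writes \code{model.json} (config, keep-list,
#' forest, AD), \code{metrics.csv}, \code{predictions.csv}
#' (substance_id, observed, predicted, in_domain), \code{prune.json} and
#' \code{run_log.json}; re-running with an identical config and data
#' reproduces these files byte for byte.
#'
#' @param fp a labelled \code{FingerprintSet} (source counts optional).
#' @param config a [runConfig()] list.
#' @param outDir output directory, or \code{NULL} to skip writing.
#' @return list with \code{forest} (selected, optimized), \code{ad},
#'   \code{split}, \code{keep} (descriptor keep-list),
#'   \code{pruneReport}, \code{candidates} (per-cost GA fitness),
#'   \code{chosenCost}, \code{gaHistory}, \code{mMetrics},
#'   \code{evaluation} (on the test set), and \code{metricsTable}.
#' @export
runProtocol <- function(fp, config = runConfig(), outDir = NULL) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    if (is.null(labelIndices(fp))) stop("stage 'input' failed: no labels")
    if (config$dedup) {
        dd <- stage("dedup",
                    dedupSubstances(substanceIds(fp), labelIndices(fp)))
        fp <- fp[, dd$keep]
        if (!is.null(dd$labels)) colData(fp)$label <- dd$labels
    }
    if (!is.null(config$minSources)) {
        keepIdx <- stage("source_filter",
                         filterMinSources(fp, config$minSources))
        fp <- fp[, keepIdx]
    }
    split <- stage("split",
                   stratifiedSplit(fp, fraction = config$splitFraction,
                                   seed = config$seed))
    fpTrain <- fp[, trainIndices(split)]
    fpTest <- fp[, testIndices(split)]
    pr <- stage("prune",
                pruneFingerprints(fpTrain, rMax = config$rMax,
                                  absolute = config$absoluteCorrelation))
    fpTrain <- pr$fp
    fpTest <- stage("prune", applyKeepList(fpTest, pr$report$keep))
    candidates <- list()
    for (ci in seq_along(config$costs)) {
        cost <- config$costs[ci]
        tc <- treeConfig(cost = cost, maxDepth = config$maxDepth,
                         nFeatureSubset = config$nFeatureSubset,
                         minNodeSize = config$minNodeSize,
                         nBins = config$nBins, fBeta = config$fBeta)
        forest <- stage("train",
                        trainForest(fpTrain, nTrees = config$nTrees,
                                    config = tc,
                                    trainFractionPerTree =
                                        config$trainFractionPerTree,
                                    seed = .deriveSeed(config$seed, ci)))
        gcfg <- config$ga
        gcfg$seed <- .deriveSeed(config$seed, 100L + ci)
        ga <- stage("optimize",
                    evolveForest(forest, fpTrain, fpTest, config = gcfg))
        candidates[[cost]] <- list(forest = forest, ga = ga)
    }
    fits <- vapply(candidates, function(c) c$ga$fitness, 0)
    chosen <- names(candidates)[which.max(fits)]
    forest <- stage("optimize",
                    applyChromosome(candidates[[chosen]]$forest,
                                    candidates[[chosen]]$ga$best))
    adBase <- stage("ad_fit",
                    fitAD(fpTrain, k = config$adK, m = config$mGrid[1L],
                          varTarget = config$varTarget))
    mOpt <- stage("ad_fit",
                  optimizeM(adBase, forest, fpTest, mGrid = config$mGrid,
                            covMin = config$covMin))
    ev <- stage("evaluate", evaluateModel(forest, fpTest, mOpt$ad))
    metricsTable <- .metricsTable(ev, forest@classNames)
    result <- list(forest = forest, ad = mOpt$ad, split = split,
                   keep = pr$report$keep, pruneReport = pr$report,
                   candidates = lapply(candidates, function(c)
                       list(fitness = c$ga$fitness,
                            identityFitness = c$ga$identityFitness)),
                   chosenCost = chosen,
                   gaHistory = candidates[[chosen]]$ga$history,
                   mMetrics = mOpt$metrics, evaluation = ev,
                   metricsTable = metricsTable)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        envelope <- list(format = "ConservativeRF-model", version = 1L,
                         config = config[setdiff(names(config), "ga")],
                         ga = config$ga[setdiff(names(config$ga), NULL)],
                         chosenCost = chosen, keep = pr$report$keep,
                         forest = .forestToList(forest),
                         ad = .adToList(mOpt$ad))
        json <- jsonlite::toJSON(envelope, auto_unbox = TRUE, digits = I(17),
                                 null = "null", na = "null")
        writeLines(json, file.path(outDir, "model.json"), useBytes = TRUE)
        utils::write.csv(metricsTable, file.path(outDir, "metrics.csv"),
                         row.names = FALSE)
        cmAll <- counts(ev$all$confusion)
        utils::write.csv(as.data.frame(cmAll),
                         file.path(outDir, "confusion_all.csv"))
        utils::write.csv(as.data.frame(counts(ev$inDomain$confusion)),
                         file.path(outDir, "confusion_in_domain.csv"))
        preds <- data.frame(substance_id = substanceIds(fpTest),
                            observed = forest@classNames[labelIndices(fpTest)],
                            predicted = forest@classNames[ev$predicted],
                            in_domain = ev$inDomainFlags)
        utils::write.csv(preds, file.path(outDir, "predictions.csv"),
                         row.names = FALSE)
        writePruneReport(pr$report, file.path(outDir, "prune.json"))
        log <- list(seed = config$seed, chosenCost = chosen,
                    nTrain = length(trainIndices(split)),
                    nTest = length(testIndices(split)),
                    nDescriptorsKept = length(pr$report$keep),
                    adM = mOpt$m,
                    package = "ConservativeRF",
                    packageVersion = as.character(
                        utils::packageVersion("ConservativeRF")),
                    rVersion = paste(R.version$major, R.version$minor,
                                     sep = "."))
        jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                             auto_unbox = TRUE, digits = NA)
        result$outDir <- outDir
    }
    result
}

#' Read/write the full model envelope
#'
#' \code{readModelJSON} restores the forest, applicability domain and
#' descriptor keep-list written by [runProtocol()].
#'
#' @param path path to a \code{model.json}.
#' @return list with \code{forest}, \code{ad}, \code{keep},
#'   \code{chosenCost}.
#' @export
readModelJSON <- function(path) {
    l <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    list(forest = .forestFromList(l$forest),
         ad = .adFromList(l$ad),
         keep = as.character(unlist(l$keep)),
         chosenCost = as.character(l$chosenCost))
}
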