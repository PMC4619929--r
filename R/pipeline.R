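#' The nine stacked-model variants
#'
#' Cross of the three classifier categories (`go2ppi`, `phyloprof`,
#' `combined`) with the three species subcategories (`SC`, `cross`,
#' `all`).
#'
#' @return data.frame with columns `category`, `subcategory`, `name`
#'   (`"category/subcategory"`).
#' @export
stackVariants <- function() {
  g <- expand.grid(subcategory = c("SC", "cross", "all"),
                   category = c("go2ppi", "phyloprof", "combined"),
                   stringsAsFactors = FALSE)
  data.frame(category = g$category, subcategory = g$subcategory,
             name = paste(g$category, g$subcategory, sep = "/"),
             stringsAsFactors = FALSE)
}

#' Repeated end-to-end evaluation of the stacking pipeline
#'
#' For each repeat: rebuilds the full base-classifier score table for the
#' target species' gold standard (taxa selection, base-learner training
#' and out-of-fold scoring are all redone with repeat-specific seeds),
#' draws a stratified train/test split, trains the requested stacked
#' variants on the training rows, and measures test AUC of each variant
#' and (optionally) of every single base classifier.
#'
#' @param bundle multi-species data bundle (see [generateBundle()]); must
#'   contain every species the evaluated grids reference.
#' @param target target species code whose gold standard is evaluated
#'   (default `"SC"`).
#' @param variants data.frame with columns `category`, `subcategory`
#'   (default: all nine from [stackVariants()]).
#' @param nRepeats evaluation repeats (default 25).
#' @param baseSeed integer base seed; repeat seeds are derived from it.
#' @param trainFraction stratified train fraction (default 0.7).
#' @param numTrees trees for base and meta forests (default 500).
#' @param oofFolds folds for out-of-fold scoring of target-network
#'   learners (default 5).
#' @param collectSingles also collect per-repeat test AUC of every single
#'   classifier column (default TRUE).
#' @return list with components:
#'   * `variants`: named list of [AUCSummary-class], keyed
#'     `"category/subcategory"`;
#'   * `singles`: named list of [AUCSummary-class] per classifier id (or
#'     NULL);
#'   * `specs`: the enumerated grid;
#'   * `nRepeats`, `baseSeed`.
#' @export
runStackedEvaluation <- function(bundle, target = "SC",
                                 variants = stackVariants(),
                                 nRepeats = 25L, baseSeed = 1L,
                                 trainFraction = 0.7, numTrees = 500L,
                                 oofFolds = 5L, collectSingles = TRUE) {
  stopifnot(all(c("category", "subcategory") %in% names(variants)))
  families <- unique(unlist(lapply(variants$category, categoryFamilies)))
  specs <- enumerateGrid(families)
  gold <- bundleSpecies(bundle, target)$gold
  pairsDf <- pairData(gold)
  vNames <- paste(variants$category, variants$subcategory, sep = "/")

  variantAUC <- matrix(NA_real_, nrow = nRepeats, ncol = nrow(variants),
                       dimnames = list(NULL, vNames))
  singleAUC <- if (collectSingles) {
    matrix(NA_real_, nrow = nRepeats, ncol = nrow(specs),
           dimnames = list(NULL, specs$id))
  }
  for (r in seq_len(nRepeats)) {
    repSeed <- deriveSeed(baseSeed, 1000L + r)
    split <- splitRepeat(gold, trainFraction, r, baseSeed)
    # supervised taxa calibration on the target network sees only the
    # training split, so held-out pairs stay unseen end to end
    table <- buildScoreTable(specs, pairsDf, bundle, target = target,
                             seed = repSeed, numTrees = numTrees,
                             oofFolds = oofFolds,
                             targetTrainingPairs = pairsDf[split$train, ])
    trainTab <- table[split$train, ]
    testTab <- table[split$test, ]
    trainLab <- pairsDf$label[split$train]
    testLab <- pairsDf$label[split$test]
    for (v in seq_len(nrow(variants))) {
      model <- trainStack(trainTab, trainLab,
                          category = variants$category[v],
                          subcategory = variants$subcategory[v],
                          seed = deriveSeed(repSeed, v),
                          numTrees = numTrees)
      variantAUC[r, v] <- aucFromScores(predictStack(model, testTab),
                                        testLab)
    }
    if (collectSingles) {
      singleAUC[r, ] <- apply(scoreMatrix(testTab), 2L, aucFromScores,
                              labels = testLab)
    }
  }
  list(
    variants = setNames(lapply(seq_len(ncol(variantAUC)), function(v) {
      aucSummary(variantAUC[, v])
    }), vNames),
    singles = if (collectSingles) {
      setNames(lapply(seq_len(ncol(singleAUC)), function(s) {
        aucSummary(singleAUC[, s])
      }), colnames(singleAUC))
    },
    specs = specs,
    nRepeats = as.integer(nRepeats),
    baseSeed = as.integer(baseSeed)
  )
}
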