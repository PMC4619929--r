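# Registered vocabularies of the two base-classifier families.
#
# phyloprof family: 3 profile scorers x 8 taxa strategies x 4 training
# networks = 96 classifiers.  go2ppi family: 2 learners x 7 GO aspect
# combos x 7 training networks = 98 classifiers.  Combined: 194.
gridRegistry <- list(
  phyloprof = list(
    methods = c("pp", "mi", "hg"),
    options = c("identity", "random_subset", "redundancy_filter",
                "tree_level_filter", "greedy_forward", "greedy_backward",
                "genetic_algorithm", "simulated_annealing"),
    networks = c("EC", "SC", "DM", "AT")
  ),
  go2ppi = list(
    methods = c("nb", "rf"),
    options = c("BP", "CC", "MF", "BPCC", "BPMF", "CCMF", "BPCCMF"),
    networks = c("HS", "MM", "SP", "SC", "AT", "EC", "DM")
  )
)

#' Enumerate the base-classifier grid
#'
#' Cross-product of the registered vocabularies of each requested family,
#' in deterministic order (family, then method, then option, then network,
#' each in registry order).  Every cell is one base classifier with
#' canonical id `family|method|option|network`.
#'
#' @param families subset of `c("phyloprof", "go2ppi")`.
#' @return data.frame with columns `family`, `method`, `option`, `network`,
#'   `id`.
#' @export
enumerateGrid <- function(families = c("phyloprof", "go2ppi")) {
  stopifnot(all(families %in% names(gridRegistry)))
  specs <- lapply(families, function(fam) {
    reg <- gridRegistry[[fam]]
    g <- expand.grid(network = reg$networks, option = reg$options,
                     method = reg$methods, stringsAsFactors = FALSE)
    data.frame(family = fam, method = g$method, option = g$option,
               network = g$network, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, specs)
  out$id <- paste(out$family, out$method, out$option, out$network, sep = "|")
  stopifnot(!anyDuplicated(out$id))
  rownames(out) <- NULL
  out
}

#' Filter classifiers by species subcategory
#'
#' `"SC"` keeps classifiers trained on the S. cerevisiae network, `"cross"`
#' keeps every other training network (cross-species classifiers), and
#' `"all"` keeps everything.
#'
#' @param specs data.frame from [enumerateGrid()].
#' @param category one of `"SC"`, `"cross"`, `"all"`.
#' @return filtered spec data.frame.
#' @export
filterCategory <- function(specs, category = c("all", "SC", "cross")) {
  category <- match.arg(category)
  keep <- switch(category,
    all = rep(TRUE, nrow(specs)),
    SC = specs$network == "SC",
    cross = specs$network != "SC")
  out <- specs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

categoryFamilies <- function(category) {
  switch(category,
    go2ppi = "go2ppi",
    phyloprof = "phyloprof",
    combined = c("phyloprof", "go2ppi"),
    stop("unknown category: ", category))
}

bundleSpecies <- function(bundle, network) {
  sp <- bundle[[network]]
  if (is.null(sp)) stop("bundle has no data for species ", network)
  sp
}

#' Build the per-pair score table of a classifier grid
#'
#' Scores every pair with every classifier spec and assembles the result
#' into a [ScoreTable-class].  For a phyloprof spec, reference taxa are
#' selected on the spec's training network (its profile matrix plus, for
#' supervised strategies, its labelled pairs) and the target pairs are then
#' scored on the target species' profiles restricted to those taxa.  For a
#' go2ppi spec, the learner is trained on the training network's labelled
#' pairs; when the training network *is* the target species the scored
#' pairs coincide with the learner's training pairs, so stratified
#' out-of-fold scores are used to prevent leakage into the meta-learner.
#' Pairs a spec cannot score (a protein absent from that spec's data) get
#' an imputed 0 with the missing-mask bit set.  Deterministic given `seed`.
#'
#' @param specs data.frame from [enumerateGrid()] (possibly filtered).
#' @param pairs data.frame of target pairs (`proteinA`, `proteinB`) with a
#'   `label` column (required for out-of-fold scoring of target-network
#'   learners).
#' @param bundle named list keyed by species code; each element a list with
#'   components `gold` ([GoldStandard-class]), `profiles`
#'   ([PhyloProfiles-class]) and `annotations` ([GOAnnotations-class]).
#' @param target species code the pairs belong to (default `"SC"`).
#' @param seed integer seed; per-spec seeds are derived from it.
#' @param numTrees trees for random-forest base learners (default 500).
#' @param oofFolds folds for out-of-fold scoring of target-network
#'   learners (default 5).
#' @param targetTrainingPairs optional labelled pair data.frame used to
#'   calibrate supervised taxa strategies whose training network *is* the
#'   target species.  Pass the evaluation's training split here so that
#'   taxa optimization never sees held-out pairs; when NULL, the target
#'   species' own gold standard is used (appropriate only when the scored
#'   pairs are not later split for evaluation).
#' @return [ScoreTable-class] with one column per spec id.
#' @export
buildScoreTable <- function(specs, pairs, bundle, target = "SC", seed = 1L,
                            numTrees = 500L, oofFolds = 5L,
                            targetTrainingPairs = NULL) {
  stopifnot(is.data.frame(specs), nrow(specs) > 0L,
            all(c("proteinA", "proteinB") %in% names(pairs)))
  missingSpecies <- setdiff(unique(specs$network), names(bundle))
  if (length(missingSpecies)) {
    stop("bundle lacks data for species: ",
         paste(missingSpecies, collapse = ", "))
  }
  nPairs <- nrow(pairs)
  scores <- matrix(0, nrow = nPairs, ncol = nrow(specs),
                   dimnames = list(NULL, specs$id))
  mask <- matrix(FALSE, nrow = nPairs, ncol = nrow(specs),
                 dimnames = list(NULL, specs$id))
  targetData <- bundleSpecies(bundle, target)
  annUnknown <- if (is.null(targetData$annotations)) {
    rep(FALSE, nPairs)
  } else {
    annProt <- proteins(targetData$annotations)
    !(pairs$proteinA %in% annProt) | !(pairs$proteinB %in% annProt)
  }

  # caches shared across specs: taxa selections per (strategy, network),
  # target features per combo, training features per (network, combo)
  taxaCache <- new.env(parent = emptyenv())
  featCache <- new.env(parent = emptyenv())

  # out-of-fold bookkeeping is done in canonical pair order (sorted by pair
  # key) so that scores are a function of pair identity, not row position:
  # permuting the input pairs permutes every score column identically
  canonOrd <- order(pairKey(pairs$proteinA, pairs$proteinB))
  invOrd <- integer(nPairs)
  invOrd[canonOrd] <- seq_len(nPairs)
  sharedFolds <- NULL
  if (!is.null(pairs$label) && any(specs$network == target &
                                   specs$family == "go2ppi")) {
    labC <- pairs$label[canonOrd]
    posC <- asPositiveLogical(labC)
    if (sum(posC) < oofFolds || sum(!posC) < oofFolds) {
      stop("need at least ", oofFolds, " pairs of each class for ",
           "out-of-fold scoring")
    }
    sharedFolds <- integer(nPairs)
    withr::with_seed(deriveSeed(seed, 999L), {
      sharedFolds[posC] <- sample(rep_len(seq_len(oofFolds), sum(posC)))
      sharedFolds[!posC] <- sample(rep_len(seq_len(oofFolds), sum(!posC)))
    })
  }

  getSelection <- function(strategy, network, specSeed) {
    key <- paste(strategy, network, sep = "::")
    if (!is.null(taxaCache[[key]])) return(taxaCache[[key]])
    sp <- bundleSpecies(bundle, network)
    if (is.null(sp$profiles)) stop("no profiles for species ", network)
    tp <- if (strategy %in% supervisedStrategies) {
      if (network == target && !is.null(targetTrainingPairs)) {
        targetTrainingPairs
      } else {
        pairData(sp$gold)
      }
    }
    sel <- selectTaxa(sp$profiles, strategy, seed = specSeed,
                      trainingPairs = tp)
    taxaCache[[key]] <- sel
    sel
  }
  getFeatures <- function(network, combo) {
    key <- paste(network, combo, sep = "::")
    if (!is.null(featCache[[key]])) return(featCache[[key]])
    sp <- bundleSpecies(bundle, network)
    p <- if (network == target) pairs else pairData(sp$gold)
    f <- pairFeatures(sp$annotations, p, combo)
    featCache[[key]] <- f
    f
  }

  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    specSeed <- deriveSeed(seed, i)
    if (spec$family == "phyloprof") {
      # taxa selection is per (strategy, network); the selection seed must
      # not depend on which of the three scorers asks first
      strategyIdx <- match(spec$option, gridRegistry$phyloprof$options)
      networkIdx <- match(spec$network, gridRegistry$phyloprof$networks)
      sel <- getSelection(spec$option, spec$network,
                          deriveSeed(seed, 10000L + 10L * strategyIdx +
                                       networkIdx))
      prof <- targetData$profiles
      known <- rownames(profileMatrix(prof))
      ok <- pairs$proteinA %in% known & pairs$proteinB %in% known
      if (any(ok)) {
        scores[ok, i] <- scoreProfilePairs(prof, pairs[ok, , drop = FALSE],
                                           method = spec$method,
                                           selected = sel)
      }
      mask[!ok, i] <- TRUE
    } else {
      feats <- getFeatures(target, spec$option)
      if (spec$network == target) {
        if (is.null(pairs$label)) {
          stop("target pairs need labels for out-of-fold scoring of ",
               spec$id)
        }
        oof <- oofScores(feats[canonOrd, , drop = FALSE],
                         pairs$label[canonOrd], learner = spec$method,
                         k = oofFolds, seed = specSeed, numTrees = numTrees,
                         folds = sharedFolds)
        scores[, i] <- oof$scores[invOrd]
      } else {
        trainFeats <- getFeatures(spec$network, spec$option)
        sp <- bundleSpecies(bundle, spec$network)
        fit <- trainBaseLearner(trainFeats, pairLabels(sp$gold),
                                learner = spec$method, seed = specSeed,
                                numTrees = numTrees)
        scores[, i] <- predictBaseLearner(fit, feats)
      }
      # proteins wholly absent from the target annotation map are
      # unscorable for this spec: impute 0 and set the mask bit
      scores[annUnknown, i] <- 0
      mask[annUnknown, i] <- TRUE
    }
  }
  new("ScoreTable",
      pairs = pairs[, c("proteinA", "proteinB"), drop = FALSE],
      scores = scores, mask = mask)
}

#' Write a score table to TSV
#'
#' Columns: `pair_id`, `protein_a`, `protein_b`, then one column per
#' classifier id.
#'
#' @param table [ScoreTable-class] object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeScoreTable <- function(table, path) {
  p <- pairData(table)
  out <- data.frame(pair_id = seq_len(nrow(p)), protein_a = p$proteinA,
                    protein_b = p$proteinB, scoreMatrix(table),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
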