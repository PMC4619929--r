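gafAspectMap <- c(P = "BP", C = "CC", F = "MF")

#' Admissible GO aspect combinations
#'
#' The seven aspect combinations a GO-based base classifier can be trained
#' on: each single aspect, each pair, and all three.
#'
#' @return character vector
#'   `c("BP","CC","MF","BPCC","BPMF","CCMF","BPCCMF")`.
#' @export
aspectCombos <- function() {
  c("BP", "CC", "MF", "BPCC", "BPMF", "CCMF", "BPCCMF")
}

comboAspects <- function(combo) {
  if (!combo %in% aspectCombos()) stop("invalid aspect combo: ", combo)
  c("BP", "CC", "MF")[vapply(c("BP", "CC", "MF"), grepl, logical(1),
                             x = combo, fixed = TRUE)]
}

#' Load GO annotations from GAF or plain TSV
#'
#' GAF 2.x input uses columns 2 (DB object ID), 5 (GO ID) and 9 (aspect,
#' one of P/C/F); `!` comment lines are skipped and term IDs must match
#' `GO:\\d{7}`.  The TSV fallback expects three columns: protein, term,
#' aspect (`BP`/`CC`/`MF` or `P`/`C`/`F`).  Duplicate (protein, term) lines
#' collapse to one set member.
#'
#' @param path path to the annotation file.
#' @param format `"gaf"` (default) or `"tsv"`.
#' @return [GOAnnotations-class] object.
#' @export
loadAnnotations <- function(path, format = c("gaf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^!", lines)]
  if (format == "tsv") lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0L) stop("no annotation rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gaf") {
    nf <- lengths(fields)
    if (any(nf < 9L)) {
      stop("GAF row with fewer than 9 columns at data line ",
           which(nf < 9L)[1])
    }
    prot <- vapply(fields, `[[`, character(1), 2L)
    term <- vapply(fields, `[[`, character(1), 5L)
    aspectCode <- vapply(fields, `[[`, character(1), 9L)
    bad <- !aspectCode %in% names(gafAspectMap)
    if (any(bad)) {
      stop("unknown GAF aspect code '", aspectCode[bad][1],
           "' at data line ", which(bad)[1])
    }
    aspect <- gafAspectMap[aspectCode]
    if (any(!grepl("^GO:\\d{7}$", term))) {
      stop("malformed GO term ID '",
           term[!grepl("^GO:\\d{7}$", term)][1], "'")
    }
  } else {
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      stop("TSV row with fewer than 3 columns at data line ",
           which(nf < 3L)[1])
    }
    prot <- vapply(fields, `[[`, character(1), 1L)
    term <- vapply(fields, `[[`, character(1), 2L)
    aspect <- vapply(fields, `[[`, character(1), 3L)
    long <- gafAspectMap[aspect]
    aspect <- ifelse(is.na(long), aspect, long)
    bad <- !aspect %in% c("BP", "CC", "MF")
    if (any(bad)) {
      stop("unknown aspect '", aspect[bad][1], "' at data line ",
           which(bad)[1])
    }
  }
  ann <- lapply(split(seq_along(prot), prot), function(idx) {
    byAspect <- split(term[idx], factor(aspect[idx],
                                        levels = c("BP", "CC", "MF")))
    lapply(byAspect, function(x) sort(unique(x)))
  })
  new("GOAnnotations", annotations = ann)
}

#' Write GO annotations as a minimal GAF 2.2 file
#'
#' @param annotations [GOAnnotations-class] object.
#' @param path output file path.
#' @param db database label for column 1 (default `"synthetic"`).
#' @return invisibly, the path.
#' @export
writeAnnotations <- function(annotations, path, db = "synthetic") {
  ann <- annotations@annotations
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  rev <- setNames(names(gafAspectMap), gafAspectMap)
  for (prot in names(ann)) {
    for (aspect in c("BP", "CC", "MF")) {
      for (term in ann[[prot]][[aspect]]) {
        writeLines(paste(db, prot, prot, "", term, "PMID:0000000", "IEA", "",
                         rev[[aspect]], "", "", "protein", "taxon:0", "20260101",
                         db, "", "", sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Pair features from GO annotations
#'
#' For each aspect in the combo (in fixed BP, CC, MF order) four overlap
#' statistics of the two proteins' term sets are emitted -- shared-term
#' count, Jaccard index, union size, and overlap ratio (shared count over
#' the smaller set size) -- followed by one missing-annotation flag per
#' aspect (1 when either protein has no terms in that aspect).  Proteins
#' absent from the annotation map contribute empty term sets, so features
#' are always defined and the vector is symmetric in the pair order.
#'
#' @param annotations [GOAnnotations-class] object.
#' @param pairs data.frame with columns `proteinA`, `proteinB`.
#' @param combo one of [aspectCombos()].
#' @return numeric matrix, one row per pair, `5 * nAspects` columns
#'   (4 overlap features per aspect + per-aspect missing flags).
#' @export
pairFeatures <- function(annotations, pairs, combo) {
  aspects <- comboAspects(combo)
  ann <- annotations@annotations
  getSets <- function(ids, aspect) {
    lapply(ids, function(p) {
      e <- ann[[p]]
      if (is.null(e)) character() else e[[aspect]]
    })
  }
  blocks <- lapply(aspects, function(aspect) {
    sa <- getSets(pairs$proteinA, aspect)
    sb <- getSets(pairs$proteinB, aspect)
    shared <- mapply(function(x, y) length(intersect(x, y)), sa, sb)
    union <- mapply(function(x, y) length(union(x, y)), sa, sb)
    minSize <- pmin(lengths(sa), lengths(sb))
    jaccard <- ifelse(union > 0, shared / union, 0)
    overlap <- ifelse(minSize > 0, shared / minSize, 0)
    missing <- as.numeric(lengths(sa) == 0L | lengths(sb) == 0L)
    # an aspect with an unannotated member carries no pair evidence: all
    # four overlap features are zeroed and only the flag speaks
    cbind(shared = shared, jaccard = jaccard,
          union = ifelse(missing == 1, 0, union),
          overlap = overlap, missing = missing)
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(aspects, function(a) {
    paste(a, c("shared", "jaccard", "union", "overlap", "missing"),
          sep = "_")
  }))
  rownames(out) <- NULL
  out
}

#' Train a GO-feature base learner
#'
#' Fits a naive Bayes (Gaussian class-conditionals, variance floored at
#' 1e-6 to tolerate constant features) or probability random forest (500
#' trees, sqrt(p) candidate features per split) on pair features, returning
#' a scorer that maps feature rows to interaction probabilities in
#' `[0, 1]`.  Deterministic for a given seed.
#'
#' @param features numeric matrix (pairs x features).
#' @param labels labels with both `"positive"` and `"negative"` present.
#' @param learner `"nb"` or `"rf"`.
#' @param seed integer seed (used by the forest).
#' @param numTrees trees in the forest (default 500).
#' @return object of class `baseLearner`; score new feature rows with
#'   [predictBaseLearner()].
#' @export
trainBaseLearner <- function(features, labels, learner = c("nb", "rf"),
                             seed = 1L, numTrees = 500L) {
  learner <- match.arg(learner)
  pos <- asPositiveLogical(labels)
  if (all(pos) || !any(pos)) stop("single-class training set")
  if (any(!is.finite(features))) stop("features must be finite")
  y <- factor(ifelse(pos, "positive", "negative"),
              levels = c("negative", "positive"))
  if (learner == "nb") {
    keep <- which(apply(features, 2L, stats::sd) > 0)
    if (length(keep) == 0L) {
      fit <- NULL  # no informative feature: fall back to the class prior
    } else {
      fit <- e1071::naiveBayes(x = features[, keep, drop = FALSE], y = y)
      # floor per-class sds so constant-within-class features stay finite
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2L] <- pmax(tb[, 2L], 1e-6)
        tb
      })
    }
    model <- list(fit = fit, keep = keep, prior = mean(pos))
  } else {
    df <- data.frame(features, check.names = FALSE)
    df$.label <- y
    model <- ranger::ranger(
      dependent.variable.name = ".label", data = df,
      num.trees = numTrees, probability = TRUE,
      seed = seed, num.threads = 1L, verbose = FALSE)
  }
  structure(list(learner = learner, model = model,
                 featureNames = colnames(features)),
            class = "baseLearner")
}

#' Score pairs with a fitted base learner
#'
#' @param object `baseLearner` from [trainBaseLearner()].
#' @param features numeric matrix with the training feature columns.
#' @return numeric vector of interaction probabilities in `[0, 1]`.
#' @export
predictBaseLearner <- function(object, features) {
  stopifnot(inherits(object, "baseLearner"))
  if (!is.null(object$featureNames)) {
    features <- features[, object$featureNames, drop = FALSE]
  }
  if (object$learner == "nb") {
    m <- object$model
    if (is.null(m$fit)) return(rep(m$prior, nrow(features)))
    p <- predict(m$fit, features[, m$keep, drop = FALSE], type = "raw")
    unname(p[, "positive"])
  } else {
    p <- predict(object$model, data = data.frame(features, check.names = FALSE),
                 num.threads = 1L, verbose = FALSE)$predictions
    unname(p[, "positive"])
  }
}

#' Out-of-fold base-learner scores
#'
#' Stratified k-fold cross-fitting: every pair is scored by a model trained
#' on folds that excluded it, so downstream stacking sees no leakage from
#' the base learner's own training pairs.
#'
#' @inheritParams trainBaseLearner
#' @param k number of folds (default 5).
#' @param folds optional integer fold assignment per pair (values in
#'   `1..k`); when NULL, a stratified assignment is drawn from `seed`.
#' @return list with `scores` (numeric vector) and `folds` (integer fold
#'   assignment per pair).
#' @export
oofScores <- function(features, labels, learner = c("nb", "rf"), k = 5L,
                      seed = 1L, numTrees = 500L, folds = NULL) {
  learner <- match.arg(learner)
  pos <- asPositiveLogical(labels)
  n <- length(pos)
  if (is.null(folds)) {
    if (sum(pos) < k || sum(!pos) < k) {
      stop("need at least k members of each class for ", k, "-fold scoring")
    }
    folds <- integer(n)
    withr::with_seed(seed, {
      folds[pos] <- sample(rep_len(seq_len(k), sum(pos)))
      folds[!pos] <- sample(rep_len(seq_len(k), sum(!pos)))
    })
  } else {
    stopifnot(length(folds) == n, all(folds %in% seq_len(k)))
    k <- max(folds)
  }
  scores <- numeric(n)
  for (f in seq_len(k)) {
    inFold <- folds == f
    fit <- trainBaseLearner(features[!inFold, , drop = FALSE],
                            labels[!inFold], learner,
                            seed = deriveSeed(seed, f), numTrees = numTrees)
    scores[inFold] <- predictBaseLearner(fit, features[inFold, , drop = FALSE])
  }
  list(scores = scores, folds = folds)
}
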