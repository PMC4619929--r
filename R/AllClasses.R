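#' GoldStandard: a labelled protein-pair dataset
#'
#' Holds canonical unordered protein pairs labelled `positive` or `negative`,
#' the protein universe the negatives were drawn from, the positive:negative
#' ratio (1:r) and the sampling seed.  Pairs are canonical: `proteinA <
#' proteinB` lexicographically, no self-pairs, no duplicates, and the
#' positive and negative sets are disjoint.
#'
#' @slot pairs data.frame with columns `proteinA`, `proteinB`, `label`.
#' @slot ratio integer r: number of negatives per positive.
#' @slot universe character vector of protein IDs the pairs are drawn from.
#' @slot seed integer seed used for negative sampling.
#' @export
setClass("GoldStandard",
  representation(pairs = "data.frame", ratio = "integer",
                 universe = "character", seed = "integer"),
  validity = function(object) {
    p <- object@pairs
    msg <- character()
    need <- c("proteinA", "proteinB", "label")
    if (!all(need %in% names(p))) {
      return(paste("pairs must have columns", paste(need, collapse = ", ")))
    }
    if (any(p$proteinA >= p$proteinB)) {
      msg <- c(msg, "pairs must be canonical (proteinA < proteinB)")
    }
    if (anyDuplicated(pairKey(p$proteinA, p$proteinB))) {
      msg <- c(msg, "duplicate pairs present")
    }
    if (!all(p$label %in% c("positive", "negative"))) {
      msg <- c(msg, "labels must be 'positive' or 'negative'")
    }
    if (!all(c(p$proteinA, p$proteinB) %in% object@universe)) {
      msg <- c(msg, "all pair members must belong to the universe")
    }
    if (length(object@ratio) != 1L || object@ratio < 1L) {
      msg <- c(msg, "ratio must be a single integer >= 1")
    }
    if (length(msg)) msg else TRUE
  }
)

#' PhyloProfiles: binary presence/absence of proteins across reference taxa
#'
#' A proteins x taxa 0/1 matrix: entry (i, j) records whether a homolog of
#' protein i is present in reference taxon j.  Co-evolving (interacting)
#' proteins tend to have correlated profile rows.
#'
#' @slot presence integer matrix with protein IDs as rownames and taxon IDs
#'   as colnames; entries in \{0, 1\}.
#' @export
setClass("PhyloProfiles",
  representation(presence = "matrix"),
  validity = function(object) {
    m <- object@presence
    msg <- character()
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      return("presence matrix needs protein rownames and taxon colnames")
    }
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate protein IDs")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate taxon IDs")
    if (!all(m %in% c(0L, 1L))) msg <- c(msg, "entries must be 0 or 1")
    if (length(msg)) msg else TRUE
  }
)

#' GOAnnotations: per-protein GO term sets split by aspect
#'
#' Maps each protein ID to three character vectors of GO term IDs, one per
#' ontology aspect: biological process (BP), cellular component (CC) and
#' molecular function (MF).
#'
#' @slot annotations named list; each element is a list with components
#'   `BP`, `CC`, `MF` (character vectors of term IDs).
#' @export
setClass("GOAnnotations",
  representation(annotations = "list"),
  validity = function(object) {
    ann <- object@annotations
    if (length(ann) == 0L) return("empty annotation map")
    if (is.null(names(ann)) || any(names(ann) == "")) {
      return("annotations must be named by protein ID")
    }
    ok <- vapply(ann, function(x) {
      is.list(x) && all(c("BP", "CC", "MF") %in% names(x))
    }, logical(1))
    if (!all(ok)) return("each entry needs BP, CC and MF term sets")
    TRUE
  }
)

#' ScoreTable: per-pair scores from a grid of base classifiers
#'
#' One row per protein pair, one column per classifier id (canonical
#' `family|method|option|network` strings).  Pairs a classifier could not
#' score (a protein missing from that classifier's data) carry an imputed 0
#' and a set bit in the missing mask.
#'
#' @slot pairs data.frame with columns `proteinA`, `proteinB` aligned to the
#'   score rows.
#' @slot scores numeric matrix (pairs x classifiers), no NA/NaN.
#' @slot mask logical matrix of the same shape; TRUE marks imputed entries.
#' @export
setClass("ScoreTable",
  representation(pairs = "data.frame", scores = "matrix", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@scores) != nrow(object@pairs)) {
      msg <- c(msg, "score rows must align with pairs")
    }
    if (!identical(dim(object@scores), dim(object@mask))) {
      msg <- c(msg, "mask must have the same shape as scores")
    }
    if (anyNA(object@scores) || any(!is.finite(object@scores))) {
      msg <- c(msg, "scores must be finite (impute before construction)")
    }
    if (is.null(colnames(object@scores))) {
      msg <- c(msg, "score columns must be named by classifier id")
    } else if (anyDuplicated(colnames(object@scores))) {
      msg <- c(msg, "duplicate classifier ids")
    }
    if (length(msg)) msg else TRUE
  }
)

#' StackedModel: the random-forests meta-classifier over base scores
#'
#' A fitted second-level random forest that consumes the per-pair score
#' vector of a fixed, ordered subset of base classifiers (one of the nine
#' category x subcategory variants) and emits an interaction probability.
#'
#' @slot category one of `"go2ppi"`, `"phyloprof"`, `"combined"`.
#' @slot subcategory one of `"SC"`, `"cross"`, `"all"`.
#' @slot featureIds ordered classifier-id character vector the model consumes.
#' @slot forest the fitted `ranger` probability forest.
#' @slot numTrees integer number of trees.
#' @slot seed integer training seed.
#' @export
setClass("StackedModel",
  representation(category = "character", subcategory = "character",
                 featureIds = "character", forest = "ANY",
                 numTrees = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@category %in% c("go2ppi", "phyloprof", "combined")) {
      msg <- c(msg, "invalid category")
    }
    if (!object@subcategory %in% c("SC", "cross", "all")) {
      msg <- c(msg, "invalid subcategory")
    }
    if (length(object@featureIds) == 0L) msg <- c(msg, "no feature ids")
    if (length(msg)) msg else TRUE
  }
)

#' ROCPoints: an ROC curve as ordered (FPR, TPR) points
#'
#' Starts at (0, 0), ends at (1, 1); both coordinates are non-decreasing.
#' Tied scores advance as a single step, so ties trace a diagonal segment.
#'
#' @slot fpr numeric vector of false-positive rates (X coordinates).
#' @slot tpr numeric vector of true-positive rates (Y coordinates).
#' @export
setClass("ROCPoints",
  representation(fpr = "numeric", tpr = "numeric"),
  validity = function(object) {
    x <- object@fpr; y <- object@tpr
    msg <- character()
    if (length(x) != length(y)) msg <- c(msg, "fpr/tpr length mismatch")
    if (length(x) < 2L) msg <- c(msg, "need at least the two endpoints")
    if (any(diff(x) < 0) || any(diff(y) < 0)) {
      msg <- c(msg, "coordinates must be non-decreasing")
    }
    if (any(x < 0 | x > 1) || any(y < 0 | y > 1)) {
      msg <- c(msg, "coordinates must lie in [0, 1]")
    }
    if (abs(x[1]) > 1e-12 || abs(y[1]) > 1e-12 ||
        abs(x[length(x)] - 1) > 1e-12 || abs(y[length(y)] - 1) > 1e-12) {
      msg <- c(msg, "curve must run from (0,0) to (1,1)")
    }
    if (length(msg)) msg else TRUE
  }
)

#' AUCSummary: repeated-evaluation AUC statistics
#'
#' Per-repeat AUC values of one classifier (or stacked model) together with
#' their mean and standard deviation.
#'
#' @slot perRepeat numeric vector of per-repeat AUC values.
#' @slot mean mean AUC.
#' @slot sd standard deviation of the per-repeat AUCs (0 for one repeat).
#' @slot nRepeats integer number of repeats.
#' @export
setClass("AUCSummary",
  representation(perRepeat = "numeric", mean = "numeric", sd = "numeric",
                 nRepeats = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nRepeats < 1L) msg <- c(msg, "nRepeats must be >= 1")
    if (length(object@perRepeat) != object@nRepeats) {
      msg <- c(msg, "perRepeat length must equal nRepeats")
    }
    if (object@mean < 0 || object@mean > 1) msg <- c(msg, "mean outside [0,1]")
    if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
    if (length(msg)) msg else TRUE
  }
)
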