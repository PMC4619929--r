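#' @describeIn GoldStandard-class pair table (`proteinA`, `proteinB`, `label`).
#' @param x object.
#' @export
setMethod("pairData", "GoldStandard", function(x) x@pairs)

#' @describeIn GoldStandard-class pair labels as a character vector.
#' @export
setMethod("pairLabels", "GoldStandard", function(x) x@pairs$label)

#' @describeIn GoldStandard-class protein universe.
#' @export
setMethod("proteins", "GoldStandard", function(x) x@universe)

#' @describeIn PhyloProfiles-class protein IDs (matrix rownames).
#' @export
setMethod("proteins", "PhyloProfiles", function(x) rownames(x@presence))

#' @describeIn PhyloProfiles-class taxon IDs (matrix colnames).
#' @export
setMethod("taxa", "PhyloProfiles", function(x) colnames(x@presence))

#' @describeIn PhyloProfiles-class the 0/1 presence matrix.
#' @export
setMethod("profileMatrix", "PhyloProfiles", function(x) x@presence)

#' @describeIn GOAnnotations-class protein IDs with any annotation.
#' @export
setMethod("proteins", "GOAnnotations", function(x) names(x@annotations))

#' @describeIn GOAnnotations-class term set of one protein in one aspect;
#'   empty character vector when the protein is unannotated.
#' @param protein protein ID.
#' @param aspect `"BP"`, `"CC"` or `"MF"`.
#' @export
setMethod("goTerms", "GOAnnotations", function(x, protein, aspect) {
  stopifnot(aspect %in% c("BP", "CC", "MF"))
  entry <- x@annotations[[protein]]
  if (is.null(entry)) character() else entry[[aspect]]
})

#' @describeIn ScoreTable-class pair table aligned with score rows.
#' @export
setMethod("pairData", "ScoreTable", function(x) x@pairs)

#' @describeIn ScoreTable-class numeric score matrix (pairs x classifiers).
#' @export
setMethod("scoreMatrix", "ScoreTable", function(x) x@scores)

#' @describeIn ScoreTable-class logical mask of imputed (unscorable) entries.
#' @export
setMethod("missingMask", "ScoreTable", function(x) x@mask)

#' @describeIn ScoreTable-class classifier ids (column names).
#' @export
setMethod("classifierIds", "ScoreTable", function(x) colnames(x@scores))

#' @describeIn StackedModel-class ordered classifier ids the model consumes.
#' @export
setMethod("featureIds", "StackedModel", function(x) x@featureIds)

#' @describeIn AUCSummary-class per-repeat AUC values.
#' @export
setMethod("aucValues", "AUCSummary", function(x) x@perRepeat)

#' @describeIn AUCSummary-class mean AUC across repeats.
#' @export
setMethod("aucMean", "AUCSummary", function(x) x@mean)

#' @describeIn AUCSummary-class standard deviation of per-repeat AUCs.
#' @export
setMethod("aucSD", "AUCSummary", function(x) x@sd)

#' @describeIn ScoreTable-class subset pairs (rows) and/or classifiers
#'   (columns); always keeps the matrix shape.
#' @param i,j row (pair) and column (classifier) indices.
#' @param ... ignored.
#' @param drop ignored; subsetting never drops dimensions.
#' @aliases [,ScoreTable-method
#' @export
setMethod("[", "ScoreTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@scores))
  if (missing(j)) j <- seq_len(ncol(x@scores))
  new("ScoreTable",
      pairs = x@pairs[i, , drop = FALSE],
      scores = x@scores[i, j, drop = FALSE],
      mask = x@mask[i, j, drop = FALSE])
})

setMethod("show", "GoldStandard", function(object) {
  p <- object@pairs
  cat("GoldStandard with", nrow(p), "pairs:",
      sum(p$label == "positive"), "positive,",
      sum(p$label == "negative"), "negative (1:", object@ratio, "),",
      length(object@universe), "proteins in universe\n")
})

setMethod("show", "PhyloProfiles", function(object) {
  m <- object@presence
  cat("PhyloProfiles:", nrow(m), "proteins x", ncol(m), "taxa;",
      "mean presence", round(mean(m), 3), "\n")
})

setMethod("show", "GOAnnotations", function(object) {
  ann <- object@annotations
  nTerms <- vapply(c("BP", "CC", "MF"), function(a) {
    length(unique(unlist(lapply(ann, `[[`, a), use.names = FALSE)))
  }, numeric(1))
  cat("GOAnnotations:", length(ann), "proteins;",
      paste(sprintf("%s: %d terms", names(nTerms), nTerms), collapse = ", "),
      "\n")
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", nrow(object@scores), "pairs x",
      ncol(object@scores), "classifiers;",
      sum(object@mask), "imputed entries\n")
})

setMethod("show", "StackedModel", function(object) {
  cat("StackedModel [", object@category, "/", object@subcategory, "]: ",
      length(object@featureIds), " base-classifier features, ",
      object@numTrees, " trees\n", sep = "")
})

setMethod("show", "AUCSummary", function(object) {
  cat(sprintf("AUCSummary: mean %.4f +/- %.4f over %d repeats\n",
              object@mean, object@sd, object@nRepeats))
})

#' Build an AUCSummary from per-repeat values
#'
#' @param perRepeat numeric vector of per-repeat AUC values.
#' @return [AUCSummary-class] object; `sd` is 0 for a single repeat (a
#'   degenerate summary, flagged by a warning).
#' @export
aucSummary <- function(perRepeat) {
  stopifnot(is.numeric(perRepeat), length(perRepeat) >= 1L,
            all(is.finite(perRepeat)))
  n <- length(perRepeat)
  if (n == 1L) warning("single repeat: sd reported as 0 (degenerate summary)")
  new("AUCSummary", perRepeat = as.numeric(perRepeat),
      mean = mean(perRepeat),
      sd = if (n == 1L) 0 else stats::sd(perRepeat),
      nRepeats = as.integer(n))
}
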