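#' Train the stacked random-forests meta-classifier
#'
#' Fits a probability random forest on the base-classifier score columns of
#' one of the nine category x subcategory variants: the feature set is
#' `filterCategory(enumerateGrid(<category families>), subcategory)` in
#' canonical enumeration order.  Defaults: 500 trees, sqrt(p) candidate
#' features per split, seeded and single-threaded so training is
#' deterministic.
#'
#' @param table [ScoreTable-class] of training pairs (its columns must
#'   cover the variant's feature ids).
#' @param labels training labels (`"positive"`/`"negative"` or logical).
#' @param category `"go2ppi"`, `"phyloprof"` or `"combined"`.
#' @param subcategory `"SC"`, `"cross"` or `"all"`.
#' @param seed integer training seed.
#' @param numTrees number of trees (default 500).
#' @return [StackedModel-class] object.
#' @export
trainStack <- function(table, labels,
                       category = c("combined", "go2ppi", "phyloprof"),
                       subcategory = c("all", "SC", "cross"),
                       seed = 1L, numTrees = 500L) {
  category <- match.arg(category)
  subcategory <- match.arg(subcategory)
  pos <- asPositiveLogical(labels)
  if (all(pos) || !any(pos)) stop("single-class labels")
  ids <- filterCategory(enumerateGrid(categoryFamilies(category)),
                        subcategory)$id
  have <- classifierIds(table)
  absent <- setdiff(ids, have)
  if (length(absent)) {
    stop("score table lacks feature columns: ",
         paste(head(absent, 3), collapse = ", "),
         if (length(absent) > 3L) " ...")
  }
  x <- scoreMatrix(table)[, ids, drop = FALSE]
  df <- data.frame(x, check.names = FALSE)
  df$.label <- factor(ifelse(pos, "positive", "negative"),
                      levels = c("negative", "positive"))
  forest <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = numTrees, probability = TRUE,
    seed = seed, num.threads = 1L, verbose = FALSE)
  new("StackedModel", category = category, subcategory = subcategory,
      featureIds = ids, forest = forest, numTrees = as.integer(numTrees),
      seed = as.integer(seed))
}

#' Predict interaction probabilities with a stacked model
#'
#' Feature columns are matched by classifier id, so the input table's
#' column order is irrelevant.
#'
#' @param model [StackedModel-class] object.
#' @param table [ScoreTable-class] of pairs to score.
#' @return numeric vector of interaction probabilities in `[0, 1]`, one per
#'   pair.
#' @export
predictStack <- function(model, table) {
  ids <- featureIds(model)
  absent <- setdiff(ids, classifierIds(table))
  if (length(absent)) {
    stop("score table lacks feature columns: ",
         paste(head(absent, 3), collapse = ", "))
  }
  x <- scoreMatrix(table)[, ids, drop = FALSE]
  p <- predict(model@forest, data = data.frame(x, check.names = FALSE),
               num.threads = 1L, verbose = FALSE)$predictions
  unname(p[, "positive"])
}
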