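#' ROC curve of a scored pair set
#'
#' Ranks pairs by descending score and traces (FPR, TPR) points.
#' Thresholds are the distinct score values, so tied scores advance as a
#' single step (a diagonal segment); the curve always starts at (0, 0) and
#' ends at (1, 1).
#'
#' @param scores numeric vector of classifier scores.
#' @param labels labels with both classes present.
#' @return [ROCPoints-class] object.
#' @export
rocCurve <- function(scores, labels) {
  pos <- asPositiveLogical(labels)
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) stop("both classes required")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  isLast <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- cumsum(p)[isLast]
  fp <- cumsum(!p)[isLast]
  new("ROCPoints", fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos))
}

#' Trapezoidal area under an ROC curve
#'
#' `AUC = 1/2 * sum_k (X_k - X_{k-1}) (Y_k + Y_{k-1})` over the ordered
#' curve points.  With tied scores grouped into single steps this equals
#' the tie-corrected Mann-Whitney statistic: the probability that a random
#' positive outranks a random negative, ties counted one half.
#'
#' @param roc [ROCPoints-class] object.
#' @return AUC in `[0, 1]`.
#' @export
aucTrapezoid <- function(roc) {
  x <- roc@fpr
  y <- roc@tpr
  sum(diff(x) * (y[-1] + y[-length(y)])) / 2
}

#' Repeated AUC evaluation
#'
#' Runs an evaluation function once per repeat with a repeat-specific seed
#' derived from `baseSeed`, collecting one AUC per repeat into an
#' [AUCSummary-class].  Any repeat failure aborts with the repeat index.
#'
#' @param evalFun function `(repeatIndex, seed) -> AUC` performing the full
#'   per-repeat retrain (split, base scoring, stacking, AUC).
#' @param nRepeats number of repeats (default 25).
#' @param baseSeed integer base seed.
#' @return [AUCSummary-class] object.
#' @export
repeatedAUC <- function(evalFun, nRepeats = 25L, baseSeed = 1L) {
  stopifnot(nRepeats >= 1L)
  vals <- vapply(seq_len(nRepeats), function(r) {
    v <- tryCatch(evalFun(r, deriveSeed(baseSeed, r)),
                  error = function(e) stop("repeat ", r, " failed: ",
                                           conditionMessage(e)))
    as.numeric(v)
  }, numeric(1))
  aucSummary(vals)
}

#' Compare a stacked model against its individual classifiers
#'
#' Reports the standard three-way comparison for one category: the mean
#' AUC over all single classifiers ("average"), the single classifier with
#' the highest mean AUC ("highest"), and the stacked model, plus the
#' percent AUC improvement of the stack over the highest single classifier
#' (rounded to integer percent) and a two-sample Welch t-test on the
#' per-repeat AUCs of the stack versus the highest single classifier.
#'
#' @param stack [AUCSummary-class] of the stacked model.
#' @param singles named list of [AUCSummary-class], one per single
#'   classifier.
#' @return list with components `average`, `highest`, `highestId`,
#'   `stackMean`, `stackSd`, `improvementPct` (rounded),
#'   `improvementPctRaw`, `pValue`.
#' @export
compareMethods <- function(stack, singles) {
  stopifnot(length(singles) >= 1L)
  means <- vapply(singles, aucMean, numeric(1))
  bestIdx <- which.max(means)
  best <- singles[[bestIdx]]
  imp <- (aucMean(stack) - aucMean(best)) / aucMean(best) * 100
  vs <- aucValues(stack); vb <- aucValues(best)
  pv <- if (stats::sd(vs) == 0 && stats::sd(vb) == 0) {
    # degenerate constant repeats: identical -> no evidence, else certain
    if (isTRUE(all.equal(mean(vs), mean(vb)))) 1 else 0
  } else {
    t.test(vs, vb)$p.value
  }
  list(average = mean(means),
       highest = aucMean(best),
       highestId = if (!is.null(names(singles))) names(singles)[bestIdx]
                   else bestIdx,
       stackMean = aucMean(stack),
       stackSd = aucSD(stack),
       improvementPct = round(imp),
       improvementPctRaw = imp,
       pValue = pv)
}
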