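#' @importFrom methods new validObject is slot
#' @importFrom stats phyper cor hclust cutree dist rnorm runif sd t.test setNames predict
#' @importFrom utils head read.delim write.table combn
NULL

# Derive a reproducible child seed from a base seed and an index.
# Kept strictly below 2^31 - 1 so the result is a valid R integer.
deriveSeed <- function(base, index) {
  stopifnot(is.numeric(base), is.numeric(index))
  as.integer((abs(base) * 100003 + abs(index) * 7919 + 1) %% 2147483647L)
}

# Canonical string key of an unordered protein pair (a < b lexicographically).
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Canonicalize two ID vectors into (a, b) with a < b; no self-pairs allowed here.
canonicalizePairs <- function(a, b) {
  data.frame(proteinA = pmin(a, b), proteinB = pmax(a, b),
             stringsAsFactors = FALSE)
}

#' Fast rank-based AUC
#'
#' Area under the ROC curve computed as the tie-corrected Mann-Whitney
#' statistic: the probability that a randomly drawn positive outscores a
#' randomly drawn negative, with ties counted one half.  Identical to the
#' trapezoidal area returned by [aucTrapezoid()] on [rocCurve()] output.
#'
#' @param scores numeric vector of classifier scores (higher = more likely
#'   interacting).
#' @param labels logical vector (or factor/character coercible via
#'   `labels == "positive"`) marking positive pairs.
#' @return AUC in `[0, 1]`.
#' @export
aucFromScores <- function(scores, labels) {
  pos <- asPositiveLogical(labels)
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) {
    stop("AUC requires both positive and negative labels")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

asPositiveLogical <- function(labels) {
  if (is.logical(labels)) return(labels)
  as.character(labels) == "positive"
}
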