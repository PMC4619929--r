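# Shared fixtures and independent oracles for the test suite.

# Build a PhyloProfiles object from 0/1 row vectors.
makeProfiles <- function(..., taxaIds = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  if (is.null(taxaIds)) taxaIds <- sprintf("T%03d", seq_len(ncol(m)))
  dimnames(m) <- list(names(rows), taxaIds)
  new("PhyloProfiles", presence = matrix(as.integer(m), nrow = nrow(m),
                                         dimnames = dimnames(m)))
}

writeTempTSV <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Brute-force AUC oracle: fraction of (positive, negative) score pairs
# correctly ordered, ties counted one half.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == "positive" | labels == TRUE]
  neg <- scores[!(labels == "positive" | labels == TRUE)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every placement of
# b's ones among the N taxa and count placements with overlap >= observed.
bruteHypergeomTail <- function(a, b) {
  N <- length(a)
  onesA <- which(a == 1)
  nB <- sum(b)
  k <- sum(a == 1 & b == 1)
  if (nB == 0) return(1)
  placements <- utils::combn(N, nB)
  hits <- sum(apply(placements, 2L, function(cols) {
    length(intersect(cols, onesA)) >= k
  }))
  hits / ncol(placements)
}

# Entropy-based mutual information oracle: H(a) + H(b) - H(a, b), base 2.
bruteMI <- function(a, b) {
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  N <- length(a)
  ha <- H(table(a) / N)
  hb <- H(table(b) / N)
  hab <- H(table(paste(a, b)) / N)
  max(ha + hb - hab, 0)
}

# Small multi-species bundle covering all seven grid networks, cached per
# session; cheap enough for grid/pipeline unit tests.
smallBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- syntheticConfig(nProteins = 80L, nTaxa = 20L, nPositives = 15L,
                             ratio = 3L, seed = 11L)
      cache <<- generateBundle(cfg)
    }
    cache
  }
})
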