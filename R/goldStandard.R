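#' Load positive PPI pairs from a pair file
#'
#' Reads a two-column TSV of interacting protein IDs (no header required,
#' lines starting with `#` skipped) or a minimal PSI-MI TAB file (`!` header
#' line allowed; only the first two columns are used, with common
#' `db:accession` prefixes stripped).  Pairs are canonicalized so that
#' `(a, b)` and `(b, a)` collapse to one pair with `a < b` lexicographically;
#' self-pairs are dropped and duplicates removed, with dropped counts
#' reported via `message()`.
#'
#' @param path path to the pair file.
#' @param format `"tsv"` (default) or `"psimitab"`.
#' @return data.frame with columns `proteinA`, `proteinB`, `label`
#'   (all `"positive"`).
#' @export
loadPositivePairs <- function(path, format = c("tsv", "psimitab")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  skipRe <- if (format == "psimitab") "^[#!]" else "^#"
  keep <- keep & !grepl(skipRe, lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no pair rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- lineNo[which(nf < 2L)[1]]
    stop("malformed row at line ", bad, ": fewer than 2 tab-separated columns")
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  if (format == "psimitab") {
    # "uniprotkb:P12345" -> "P12345"; keep bare IDs untouched
    a <- sub("^[A-Za-z0-9_-]+:", "", a)
    b <- sub("^[A-Za-z0-9_-]+:", "", b)
  }
  empty <- !nzchar(trimws(a)) | !nzchar(trimws(b))
  if (any(empty)) {
    stop("malformed row at line ", lineNo[which(empty)[1]], ": empty protein ID")
  }
  selfPair <- a == b
  nSelf <- sum(selfPair)
  p <- canonicalizePairs(a[!selfPair], b[!selfPair])
  nDup <- sum(duplicated(pairKey(p$proteinA, p$proteinB)))
  p <- p[!duplicated(pairKey(p$proteinA, p$proteinB)), , drop = FALSE]
  if (nrow(p) == 0L) stop("no valid pairs left after filtering in ", path)
  message("loaded ", nrow(p), " positive pairs (dropped ", nSelf,
          " self-pairs, ", nDup, " duplicates)")
  p$label <- "positive"
  rownames(p) <- NULL
  p
}

#' Sample negative pairs by random pairing
#'
#' Draws exactly `ratio * nrow(positives)` distinct canonical protein pairs
#' from the universe, excluding self-pairs and any pair present in the
#' positive set.  Deterministic for a given seed.
#'
#' @param universe character vector of protein IDs to pair.
#' @param positives data.frame of canonical positive pairs (`proteinA`,
#'   `proteinB`).
#' @param ratio integer r: negatives per positive.
#' @param seed integer RNG seed.
#' @return data.frame with columns `proteinA`, `proteinB`,
#'   `label = "negative"`.
#' @export
sampleNegatives <- function(universe, positives, ratio, seed) {
  universe <- sort(unique(universe))
  n <- length(universe)
  if (n < 3L) stop("universe too small: need at least 3 proteins, got ", n)
  ratio <- as.integer(ratio)
  stopifnot(ratio >= 1L)
  posKeys <- pairKey(positives$proteinA, positives$proteinB)
  need <- ratio * nrow(positives)
  avail <- choose(n, 2) - length(unique(posKeys))
  if (avail < need) {
    stop("insufficient universe: need ", need, " negative pairs but only ",
         avail, " non-positive pairs exist (short by ", need - avail, ")")
  }
  withr::with_seed(seed, {
    if (choose(n, 2) <= 2e5) {
      # small universe: enumerate the complement and sample exactly
      idx <- combn(n, 2)
      all <- canonicalizePairs(universe[idx[1L, ]], universe[idx[2L, ]])
      keys <- pairKey(all$proteinA, all$proteinB)
      pool <- which(!(keys %in% posKeys))
      take <- sample(pool, need)
      neg <- all[take, , drop = FALSE]
    } else {
      # large universe: rejection sampling with a dedupe set
      seen <- character(0)
      negA <- character(0)
      negB <- character(0)
      while (length(negA) < need) {
        m <- max(2L * (need - length(negA)), 1000L)
        a <- universe[sample.int(n, m, replace = TRUE)]
        b <- universe[sample.int(n, m, replace = TRUE)]
        ok <- a != b
        cand <- canonicalizePairs(a[ok], b[ok])
        keys <- pairKey(cand$proteinA, cand$proteinB)
        ok2 <- !(keys %in% posKeys) & !(keys %in% seen) & !duplicated(keys)
        cand <- cand[ok2, , drop = FALSE]
        keep <- seq_len(min(nrow(cand), need - length(negA)))
        negA <- c(negA, cand$proteinA[keep])
        negB <- c(negB, cand$proteinB[keep])
        seen <- c(seen, keys[ok2][keep])
      }
      neg <- data.frame(proteinA = negA, proteinB = negB,
                        stringsAsFactors = FALSE)
    }
    neg$label <- "negative"
    rownames(neg) <- NULL
    neg
  })
}

#' Assemble a gold-standard dataset
#'
#' Combines curated positive pairs with randomly sampled negatives at a
#' 1:`ratio` positive-to-negative ratio.  By default the universe is the set
#' of proteins appearing in the positive pairs; pass `universe` to draw
#' negatives from a wider protein list.
#'
#' @param positives data.frame of positive pairs (as from
#'   [loadPositivePairs()]) or a two-column data.frame of IDs.
#' @param universe optional character vector of protein IDs; defaults to the
#'   proteins of the positive set.
#' @param ratio integer r (default 100, the conventional 1:100 imbalance).
#' @param seed integer RNG seed.
#' @return [GoldStandard-class] object.
#' @export
assembleGoldStandard <- function(positives, universe = NULL, ratio = 100L,
                                 seed = 1L) {
  stopifnot(is.data.frame(positives),
            all(c("proteinA", "proteinB") %in% names(positives)))
  pos <- canonicalizePairs(positives$proteinA, positives$proteinB)
  if (any(pos$proteinA == pos$proteinB)) stop("self-pairs in positives")
  pos <- pos[!duplicated(pairKey(pos$proteinA, pos$proteinB)), , drop = FALSE]
  pos$label <- "positive"
  if (is.null(universe)) {
    universe <- sort(unique(c(pos$proteinA, pos$proteinB)))
  } else {
    universe <- sort(unique(universe))
    if (!all(c(pos$proteinA, pos$proteinB) %in% universe)) {
      stop("positive pairs contain proteins outside the given universe")
    }
  }
  neg <- sampleNegatives(universe, pos, ratio, seed)
  allPairs <- rbind(pos, neg)
  rownames(allPairs) <- NULL
  message("gold standard: ", nrow(pos), " positives + ", nrow(neg),
          " negatives (1:", ratio, ") over ", length(universe), " proteins")
  new("GoldStandard", pairs = allPairs, ratio = as.integer(ratio),
      universe = universe, seed = as.integer(seed))
}

#' Stratified train/test split for one evaluation repeat
#'
#' Splits the pair set into disjoint train and test subsets preserving the
#' positive:negative ratio in both.  The split seed is derived from
#' `baseSeed` and `repeatIndex`, so different repeats give different but
#' reproducible partitions.
#'
#' @param gold [GoldStandard-class] object (or a data.frame with a `label`
#'   column).
#' @param trainFraction fraction of each class assigned to training
#'   (default 0.7).
#' @param repeatIndex integer repeat number (1-based).
#' @param baseSeed integer base seed shared by all repeats.
#' @return list with integer index vectors `train` and `test` into the pair
#'   rows.
#' @export
splitRepeat <- function(gold, trainFraction = 0.7, repeatIndex = 1L,
                        baseSeed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  labels <- if (is(gold, "GoldStandard")) pairLabels(gold) else gold$label
  pos <- which(labels == "positive")
  neg <- which(labels == "negative")
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present before splitting")
  }
  seed <- deriveSeed(baseSeed, repeatIndex)
  withr::with_seed(seed, {
    nPosTrain <- round(trainFraction * length(pos))
    nNegTrain <- round(trainFraction * length(neg))
    if (nPosTrain == 0L || nPosTrain == length(pos) ||
        nNegTrain == 0L || nNegTrain == length(neg)) {
      stop("trainFraction ", trainFraction,
           " would leave a class empty in train or test")
    }
    posTrain <- sample(pos, nPosTrain)
    negTrain <- sample(neg, nNegTrain)
    train <- sort(c(posTrain, negTrain))
    test <- sort(setdiff(c(pos, neg), train))
    list(train = train, test = test)
  })
}

#' Write a gold standard to TSV
#'
#' Columns: `pair_id`, `protein_a`, `protein_b`, `label`.
#'
#' @param gold [GoldStandard-class] object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGoldStandard <- function(gold, path) {
  p <- pairData(gold)
  out <- data.frame(pair_id = seq_len(nrow(p)), protein_a = p$proteinA,
                    protein_b = p$proteinB, label = p$label)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
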