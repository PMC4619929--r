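test_that("positive pair import canonicalizes, deduplicates and drops self-pairs", {
  path <- writeTempTSV(c("P1\tP2", "P2\tP1", "P3\tP3", "P1\tP2"))
  expect_message(p <- loadPositivePairs(path), "1 self-pairs, 2 duplicates")
  expect_equal(nrow(p), 1L)
  expect_equal(p$proteinA, "P1")
  expect_equal(p$proteinB, "P2")
  expect_equal(p$label, "positive")

  path2 <- writeTempTSV(c("B\tA", "C\tA"))
  p2 <- suppressMessages(loadPositivePairs(path2))
  expect_equal(p2$proteinA, c("A", "A"))
  expect_equal(p2$proteinB, c("B", "C"))
})

test_that("pair import handles comments, PSI-MI TAB prefixes, and rejects bad rows", {
  path <- writeTempTSV(c("# comment", "P1\tP2", "", "P3\tP4"))
  expect_equal(nrow(suppressMessages(loadPositivePairs(path))), 2L)

  tab <- writeTempTSV(c("!ID(A)\tID(B)\textra",
                        "uniprotkb:P2\tuniprotkb:P1\tmore\tcols",
                        "uniprotkb:P9\tuniprotkb:P3\tx\ty"))
  p <- suppressMessages(loadPositivePairs(tab, format = "psimitab"))
  expect_equal(p$proteinA, c("P1", "P3"))
  expect_equal(p$proteinB, c("P2", "P9"))

  bad <- writeTempTSV(c("P1\tP2", "loneField"))
  expect_error(loadPositivePairs(bad), "line 2")
  onlySelf <- writeTempTSV("P1\tP1")
  expect_error(suppressMessages(loadPositivePairs(onlySelf)), "no valid pairs")
  expect_error(loadPositivePairs(writeTempTSV("# nothing")), "no pair rows")
})

test_that("negative sampling meets its contract on small universes", {
  pos <- data.frame(proteinA = "A", proteinB = "B")
  neg <- sampleNegatives(LETTERS[1:6], pos, ratio = 2L, seed = 5L)
  expect_equal(nrow(neg), 2L)
  expect_false(any(neg$proteinA == "A" & neg$proteinB == "B"))
  expect_true(all(neg$proteinA < neg$proteinB))
  expect_false(anyDuplicated(paste(neg$proteinA, neg$proteinB)) > 0)

  # exhausted universe: all 45 pairs of 10 proteins are positive
  idx <- t(utils::combn(10, 2))
  allPos <- data.frame(proteinA = LETTERS[idx[, 1]],
                       proteinB = LETTERS[idx[, 2]])
  expect_error(sampleNegatives(LETTERS[1:10], allPos, 1L, 1L),
               "insufficient universe")

  # only (B,C) remains but two negatives are requested
  pos2 <- data.frame(proteinA = c("A", "A"), proteinB = c("B", "C"))
  expect_error(sampleNegatives(c("A", "B", "C"), pos2, 1L, 1L),
               "short by 1")
  expect_error(sampleNegatives(c("A", "B"), pos, 1L, 1L), "universe too small")
})

test_that("negative sampling is deterministic and respects exact counts", {
  pos <- data.frame(proteinA = c("P01", "P02"), proteinB = c("P05", "P07"))
  universe <- sprintf("P%02d", 1:30)
  n1 <- sampleNegatives(universe, pos, 10L, seed = 42L)
  n2 <- sampleNegatives(universe, pos, 10L, seed = 42L)
  n3 <- sampleNegatives(universe, pos, 10L, seed = 43L)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  expect_equal(nrow(n1), 20L)
})

test_that("sampled negatives never collide with positives across many configurations", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(5:15, 1)
    universe <- sprintf("U%02d", seq_len(n))
    idx <- t(utils::combn(n, 2))
    nPos <- sample(1:3, 1)
    take <- sample(nrow(idx), nPos)
    pos <- data.frame(proteinA = universe[idx[take, 1]],
                      proteinB = universe[idx[take, 2]])
    r <- sample(1:3, 1)
    if (choose(n, 2) - nPos < r * nPos) next
    neg <- sampleNegatives(universe, pos, r, seed = i)
    expect_equal(nrow(neg), r * nPos)
    expect_true(all(neg$proteinA < neg$proteinB))
    keys <- paste(neg$proteinA, neg$proteinB)
    expect_false(any(keys %in% paste(pos$proteinA, pos$proteinB)))
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("gold-standard assembly yields 1:r composition and valid objects", {
  pos <- data.frame(proteinA = c("A", "B", "C"), proteinB = c("B", "C", "D"))
  gs <- suppressMessages(
    assembleGoldStandard(pos, universe = LETTERS[1:10], ratio = 2L,
                         seed = 3L))
  expect_s4_class(gs, "GoldStandard")
  expect_equal(nrow(pairData(gs)), 9L)
  expect_equal(sum(pairLabels(gs) == "negative"), 6L)
  expect_true(validObject(gs))

  posBig <- data.frame(proteinA = sprintf("Q%03d", 1:5),
                       proteinB = sprintf("Q%03d", 101:105))
  gsBig <- suppressMessages(
    assembleGoldStandard(posBig, universe = sprintf("Q%03d", 1:200),
                         ratio = 100L, seed = 1L))
  expect_equal(nrow(pairData(gsBig)), 505L)

  expect_error(
    suppressMessages(assembleGoldStandard(pos, universe = c("A", "B"),
                                          ratio = 1L)),
    "outside the given universe")
})

test_that("gold-standard TSV round-trips through the pair reader", {
  gs <- suppressMessages(assembleGoldStandard(
    data.frame(proteinA = c("A", "B"), proteinB = c("C", "D")),
    universe = LETTERS[1:12], ratio = 3L, seed = 8L))
  path <- tempfile(fileext = ".tsv")
  writeGoldStandard(gs, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("pair_id", "protein_a", "protein_b", "label"))
  expect_equal(nrow(tab), nrow(pairData(gs)))
  expect_equal(tab$label, pairLabels(gs))
})

test_that("stratified splits preserve class ratios and vary by repeat", {
  pairs <- data.frame(
    proteinA = sprintf("A%04d", 1:1010),
    proteinB = sprintf("B%04d", 1:1010),
    label = c(rep("positive", 10), rep("negative", 1000)))
  sp <- splitRepeat(pairs, 0.7, repeatIndex = 1L, baseSeed = 7L)
  expect_equal(sum(pairs$label[sp$train] == "positive"), 7L)
  expect_equal(sum(pairs$label[sp$train] == "negative"), 700L)
  expect_equal(sum(pairs$label[sp$test] == "positive"), 3L)
  expect_equal(sum(pairs$label[sp$test] == "negative"), 300L)
  expect_length(intersect(sp$train, sp$test), 0L)

  sp2 <- splitRepeat(pairs, 0.7, repeatIndex = 2L, baseSeed = 7L)
  expect_false(identical(sp$train, sp2$train))
  expect_identical(sp, splitRepeat(pairs, 0.7, 1L, 7L))

  tiny <- data.frame(proteinA = c("a", "b", "c", "d"),
                     proteinB = c("e", "f", "g", "h"),
                     label = c("positive", "positive", "negative", "negative"))
  expect_error(splitRepeat(tiny, 0.999, 1L, 1L), "empty")
  expect_error(splitRepeat(data.frame(label = rep("positive", 4)), 0.5, 1L, 1L),
               "both classes")
})
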