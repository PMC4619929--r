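test_that("configuration validates probabilities and feasibility", {
  expect_s3_class(syntheticConfig(), "syntheticConfig")
  expect_error(syntheticConfig(coevolutionStrength = 1.2), "\\[0, 1\\]")
  expect_error(syntheticConfig(nProteins = 2), "positive")
  expect_error(syntheticConfig(nProteins = 10, nPositives = 60),
               "more positives")
  expect_error(syntheticConfig(nProteins = 12, nPositives = 30, ratio = 10),
               "universe too small")
})

test_that("bundles are deterministic per seed and species-structured", {
  cfg <- syntheticConfig(species = c("SC", "EC"), nProteins = 40L,
                         nTaxa = 12L, nPositives = 8L, ratio = 2L, seed = 5L)
  b1 <- generateBundle(cfg)
  b2 <- generateBundle(cfg)
  expect_identical(profileMatrix(b1$SC$profiles),
                   profileMatrix(b2$SC$profiles))
  expect_identical(b1$EC$annotations@annotations,
                   b2$EC$annotations@annotations)
  expect_identical(pairData(b1$SC$gold), pairData(b2$SC$gold))

  cfg3 <- syntheticConfig(species = c("SC", "EC"), nProteins = 40L,
                          nTaxa = 12L, nPositives = 8L, ratio = 2L, seed = 6L)
  b3 <- generateBundle(cfg3)
  expect_false(identical(profileMatrix(b1$SC$profiles),
                         profileMatrix(b3$SC$profiles)))

  # disjoint protein spaces, shared taxa and GO vocabularies
  expect_length(intersect(proteins(b1$SC$profiles),
                          proteins(b1$EC$profiles)), 0L)
  expect_identical(taxa(b1$SC$profiles), taxa(b1$EC$profiles))
  scTerms <- unique(unlist(lapply(b1$SC$annotations@annotations, unlist)))
  ecTerms <- unique(unlist(lapply(b1$EC$annotations@annotations, unlist)))
  expect_gt(length(intersect(scTerms, ecTerms)), 0L)
})

test_that("full co-evolution forces identical profiles for planted pairs", {
  cfg <- syntheticConfig(species = "SC", nProteins = 60L, nTaxa = 20L,
                         nPositives = 12L, ratio = 2L,
                         coevolutionStrength = 1, seed = 9L)
  b <- generateBundle(cfg)
  pos <- b$SC$positives
  s <- scoreProfilePairs(b$SC$profiles, pos, "pp")
  expect_true(all(s == 1))
})

test_that("planted signal lifts positive-pair scores above negatives", {
  cfg <- syntheticConfig(species = "SC", nProteins = 150L, nTaxa = 40L,
                         nPositives = 50L, ratio = 10L,
                         coevolutionStrength = 0.8, goSharingStrength = 0.8,
                         seed = 21L)
  b <- generateBundle(cfg)
  gp <- pairData(b$SC$gold)
  mi <- scoreProfilePairs(b$SC$profiles, gp, "mi")
  w <- wilcox.test(mi[gp$label == "positive"], mi[gp$label == "negative"],
                   alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.01)

  feats <- pairFeatures(b$SC$annotations, gp, "BPCCMF")
  shared <- feats[, "BP_shared"] + feats[, "CC_shared"] + feats[, "MF_shared"]
  w2 <- wilcox.test(shared[gp$label == "positive"],
                    shared[gp$label == "negative"],
                    alternative = "greater", exact = FALSE)
  expect_lt(w2$p.value, 0.01)
})

test_that("profile-scorer AUC rises monotonically with co-evolution strength", {
  meanAUC <- vapply(c(0, 0.3, 0.6, 0.9), function(strength) {
    aucs <- vapply(1:25, function(r) {
      cfg <- syntheticConfig(species = "SC", nProteins = 60L, nTaxa = 25L,
                             nPositives = 15L, ratio = 4L,
                             coevolutionStrength = strength,
                             goSharingStrength = 0, seed = 1000L + r)
      b <- generateBundle(cfg)
      gp <- pairData(b$SC$gold)
      aucFromScores(scoreProfilePairs(b$SC$profiles, gp, "pp"), gp$label)
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_identical(order(meanAUC), 1:4)  # Spearman rho = 1 over the 4 levels
})

test_that("written bundles round-trip through the package loaders", {
  cfg <- syntheticConfig(species = c("SC", "EC"), nProteins = 30L,
                         nTaxa = 10L, nPositives = 6L, ratio = 2L,
                         backgroundTermRate = 0.15, seed = 13L)
  b <- generateBundle(cfg)
  dir <- tempfile("bundle")
  writeBundle(b, dir)

  prof <- loadProfiles(file.path(dir, "SC_profiles.tsv"))
  expect_identical(profileMatrix(prof), profileMatrix(b$SC$profiles))

  pos <- suppressMessages(
    loadPositivePairs(file.path(dir, "SC_positives.tsv")))
  expected <- b$SC$positives[, c("proteinA", "proteinB")]
  rownames(expected) <- NULL
  expect_identical(pos[, c("proteinA", "proteinB")], expected)

  ann <- loadAnnotations(file.path(dir, "SC_annotations.gaf"))
  inMem <- b$SC$annotations@annotations
  annotated <- names(inMem)[vapply(inMem, function(e) any(lengths(e) > 0),
                                   logical(1))]
  expect_setequal(proteins(ann), annotated)
  for (p in annotated) {
    for (aspect in c("BP", "CC", "MF")) {
      expect_identical(goTerms(ann, p, aspect), inMem[[p]][[aspect]])
    }
  }

  b2 <- generateBundle(syntheticConfig(species = c("SC", "EC"),
                                       nProteins = 30L, nTaxa = 10L,
                                       nPositives = 6L, ratio = 2L,
                                       seed = 14L))
  expect_false(identical(profileMatrix(b$SC$profiles),
                         profileMatrix(b2$SC$profiles)))
})
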