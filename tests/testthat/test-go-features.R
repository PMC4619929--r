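gafLine <- function(prot, term, aspect) {
  paste("db", prot, prot, "", term, "PMID:1", "IEA", "", aspect, "", "",
        "protein", "taxon:0", "20260101", "db", "", "", sep = "\t")
}

test_that("GAF parsing maps aspects, collapses duplicates and rejects bad codes", {
  path <- writeTempTSV(c("!gaf-version: 2.2",
                         gafLine("P1", "GO:0000001", "P"),
                         gafLine("P1", "GO:0000002", "C"),
                         gafLine("P1", "GO:0000003", "F"),
                         gafLine("P1", "GO:0000001", "P")))
  ann <- loadAnnotations(path)
  expect_s4_class(ann, "GOAnnotations")
  expect_equal(goTerms(ann, "P1", "BP"), "GO:0000001")
  expect_equal(goTerms(ann, "P1", "CC"), "GO:0000002")
  expect_equal(goTerms(ann, "P1", "MF"), "GO:0000003")
  expect_equal(goTerms(ann, "unseen", "BP"), character())

  expect_error(loadAnnotations(writeTempTSV(gafLine("P1", "GO:0000001", "Z"))),
               "unknown GAF aspect code 'Z'")
  expect_error(loadAnnotations(writeTempTSV(gafLine("P1", "GO:1", "P"))),
               "malformed GO term")
  expect_error(loadAnnotations(writeTempTSV("!only-comments")), "no annotation")
})

test_that("TSV fallback and GAF writer round-trip annotations", {
  path <- writeTempTSV(c("P1\tGO:0000001\tBP", "P1\tGO:0000009\tMF",
                         "P2\tGO:0000002\tC"))
  ann <- loadAnnotations(path, format = "tsv")
  expect_equal(goTerms(ann, "P1", "MF"), "GO:0000009")
  expect_equal(goTerms(ann, "P2", "CC"), "GO:0000002")
  expect_error(loadAnnotations(writeTempTSV("P1\tGO:0000001\tXX"), format = "tsv"),
               "unknown aspect")

  out <- tempfile(fileext = ".gaf")
  writeAnnotations(ann, out)
  back <- loadAnnotations(out)
  expect_identical(back@annotations, ann@annotations)
})

test_that("pair features implement the documented overlap statistics", {
  ann <- new("GOAnnotations", annotations = list(
    A = list(BP = c("g1", "g2", "g3"), CC = c("c1"), MF = character()),
    B = list(BP = c("g2", "g3", "g4"), CC = c("c1"), MF = character()),
    C = list(BP = character(), CC = character(), MF = character())))
  f <- pairFeatures(ann, data.frame(proteinA = "A", proteinB = "B"), "BP")
  expect_equal(unname(f[1, "BP_shared"]), 2)
  expect_equal(unname(f[1, "BP_jaccard"]), 0.5)
  expect_equal(unname(f[1, "BP_union"]), 4)
  expect_equal(unname(f[1, "BP_overlap"]), 2 / 3)
  expect_equal(unname(f[1, "BP_missing"]), 0)

  ident <- pairFeatures(ann, data.frame(proteinA = "B", proteinB = "B"), "CC")
  expect_equal(unname(ident[1, "CC_jaccard"]), 1)
  expect_equal(unname(ident[1, "CC_shared"]), 1)

  disj <- pairFeatures(ann, data.frame(proteinA = "A", proteinB = "C"), "BP")
  expect_equal(unname(disj[1, "BP_shared"]), 0)
  expect_equal(unname(disj[1, "BP_jaccard"]), 0)
  expect_equal(unname(disj[1, "BP_missing"]), 1)

  # unknown proteins yield zero features plus missing flags, not errors
  u <- pairFeatures(ann, data.frame(proteinA = "A", proteinB = "nope"),
                    "BPCCMF")
  expect_equal(ncol(u), 15L)
  expect_true(all(u[1, grepl("missing", colnames(u))] == 1))
  expect_true(all(u[1, !grepl("missing", colnames(u))] == 0))
})

test_that("pair features are symmetric and sized 5 per aspect in fixed order", {
  ann <- smallBundle()$SC$annotations
  pairs <- head(pairData(smallBundle()$SC$gold), 25)
  for (combo in aspectCombos()) {
    f1 <- pairFeatures(ann, pairs, combo)
    f2 <- pairFeatures(ann, data.frame(proteinA = pairs$proteinB,
                                       proteinB = pairs$proteinA), combo)
    expect_identical(f1, f2)
    expect_equal(ncol(f1), 5L * nchar(combo) / 2L)
  }
  f <- pairFeatures(ann, pairs, "BPCCMF")
  expect_equal(grep("^BP_", colnames(f)), 1:5)  # fixed BP, CC, MF order
  expect_equal(grep("^MF_", colnames(f)), 11:15)
})

test_that("base learners separate separable data and are seed-deterministic", {
  x <- cbind(feat = c(rnorm(30, 2), rnorm(60, -2)))
  y <- c(rep("positive", 30), rep("negative", 60))
  for (learner in c("nb", "rf")) {
    fit <- trainBaseLearner(x, y, learner, seed = 4L)
    s <- predictBaseLearner(fit, x)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(aucFromScores(s, y), 1.0)
  }
  f1 <- trainBaseLearner(x, y, "rf", seed = 4L)
  f2 <- trainBaseLearner(x, y, "rf", seed = 4L)
  expect_identical(predictBaseLearner(f1, x), predictBaseLearner(f2, x))
  expect_error(trainBaseLearner(x, rep("positive", 90), "nb"),
               "single-class")
})

test_that("constant features do not break the Gaussian naive Bayes", {
  x <- cbind(informative = c(rnorm(20, 1), rnorm(20, -1)),
             constant = rep(0, 40))
  y <- rep(c("positive", "negative"), each = 20)
  fit <- trainBaseLearner(x, y, "nb")
  s <- predictBaseLearner(fit, x)
  expect_true(all(is.finite(s)))
  allConst <- trainBaseLearner(cbind(z = rep(1, 40)), y, "nb")
  expect_equal(predictBaseLearner(allConst, cbind(z = rep(1, 5))),
               rep(0.5, 5))
})

test_that("label permutation drives cross-validated AUC to chance", {
  set.seed(5)
  x <- cbind(a = rnorm(200), b = rnorm(200))
  aucs <- vapply(1:25, function(r) {
    y <- sample(rep(c("positive", "negative"), each = 100))
    oofScores(x, y, "nb", k = 5L, seed = r)$scores |>
      aucFromScores(y)
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("out-of-fold scores come from models that never saw the scored pair", {
  set.seed(8)
  x <- cbind(f1 = rnorm(80), f2 = rnorm(80))
  y <- rep(c("positive", "negative"), each = 40)
  oof <- oofScores(x, y, "nb", k = 4L, seed = 2L)
  expect_equal(sort(unique(oof$folds)), 1:4)
  for (f in 1:4) {
    inFold <- oof$folds == f
    refit <- trainBaseLearner(x[!inFold, , drop = FALSE], y[!inFold], "nb")
    expect_equal(oof$scores[inFold],
                 predictBaseLearner(refit, x[inFold, , drop = FALSE]))
  }
})
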