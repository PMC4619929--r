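# ppiMerge

Stacked merging of protein–protein interaction (PPI) classifiers.

No single computational PPI predictor is reliable on its own: phylogenetic
profiling works from co-evolution signal across genomes, Gene Ontology (GO)
based learners work from annotation overlap, and each sees only part of the
evidence. `ppiMerge` implements the stacking approach to this problem: a
large grid of weak base classifiers scores every candidate protein pair,
and a random-forests meta-classifier is trained on the resulting score
vectors to produce a single, stronger interaction probability. The package
is aimed at computational biologists building or benchmarking PPI
prediction pipelines, in particular for transferring predictors trained on
well-annotated model-species networks to poorly annotated target species.

## The method

**Base classifiers.** The grid has two families, 194 classifiers in total:

* *Phylogenetic-profile family* (3 scorers × 8 reference-taxa selection
  strategies × 4 training networks = 96). Each protein has a binary
  profile x ∈ {0,1}^N over N reference taxa. For a pair (a, b) over a
  selected taxa subset the scorers are
  - co-occurrence: `1 − Hamming(x_a, x_b) / N`,
  - mutual information: plug-in `MI(x_a; x_b)` in bits,
  - hypergeometric: `−log10 P(X ≥ k)` with
    `X ~ Hypergeom(N, K, n)`, where K and n are the presence counts of a
    and b and k their co-occurrence count.

  The eight taxa-selection strategies range from no-op (`identity`) and
  unsupervised filters (`random_subset`, `redundancy_filter`,
  `tree_level_filter`) to supervised searches that maximize training AUC
  of the co-occurrence scorer (`greedy_forward`, `greedy_backward`,
  `genetic_algorithm`, `simulated_annealing`).

* *GO family* (2 learners × 7 aspect combinations × 7 training networks
  = 98). For each GO aspect (BP, CC, MF) in the combination, a pair is
  described by shared-term count, Jaccard index, union size, overlap
  ratio, and a missing-annotation flag; a Gaussian naive Bayes or a
  500-tree random forest maps the features to an interaction probability.

Each classifier is tied to a *training network* (species): `SC`
(S. cerevisiae) classifiers are calibrated on the target network itself
(with out-of-fold scoring so no pair is scored by a model that saw it),
while *cross-species* classifiers are trained on another species' network
and transferred.

**Meta-classifier.** For a category (GO family, profile family, or both
combined) and a species subcategory (`SC`, `cross`, `all`) — nine variants
in total — a probability random forest (500 trees, √p features per split)
is trained on the base-score columns of the training pairs and applied to
held-out pairs.

**Evaluation.** The gold standard combines curated positive pairs with
negatives drawn by random pairing at ratio 1:r (default 1:100; the AUC is
insensitive to r). Performance is the area under the ROC curve,

    AUC = ½ Σ_k (X_k − X_{k−1}) (Y_k + Y_{k−1}),

with X = FPR, Y = TPR over the ranked pair list (ties advance as one
step), averaged over repeated stratified train/test splits and compared
against the best single classifier with a Welch t-test.

## Worked example

Synthetic data stand in for curated interaction databases, profile
databases and GO annotation files; planted signal is split between the
profile and GO channels so that neither family alone captures it.

```r
library(ppiMerge)

bundle <- generateBundle(syntheticConfig(nProteins = 120, nPositives = 30,
                                         ratio = 5, seed = 42))
bundle$SC$gold
#> GoldStandard with 180 pairs: 30 positive, 150 negative (1: 5 ), 120 proteins in universe

res <- runStackedEvaluation(
  bundle, nRepeats = 5, baseSeed = 42,
  variants = data.frame(category = c("combined", "go2ppi", "phyloprof"),
                        subcategory = "all"))
for (nm in names(res$variants)) { cat(nm, ": "); show(res$variants[[nm]]) }
#> combined/all : AUCSummary: mean 0.9956 +/- 0.0061 over 5 repeats
#> go2ppi/all : AUCSummary: mean 0.9835 +/- 0.0277 over 5 repeats
#> phyloprof/all : AUCSummary: mean 0.9410 +/- 0.0469 over 5 repeats

singleMeans <- vapply(res$singles, aucMean, numeric(1))
cmp <- compareMethods(res$variants[["combined/all"]],
                      res$singles[names(which.max(singleMeans))])
cat(sprintf("best single: %s (mean AUC %.3f)\n", cmp$highestId, cmp$highest))
#> best single: go2ppi|rf|BPCCMF|DM (mean AUC 0.991)
```

The combined stack (194 features) sits above both family-restricted stacks
and at or above the best of the 194 single classifiers; the family stacks
each lose the signal carried by the other data channel. Real pair lists,
profile matrices and GAF files enter through `loadPositivePairs()`,
`loadProfiles()`, `loadAnnotations()` and `assembleGoldStandard()`; a thin
command-line wrapper lives in `inst/scripts/ppimerge.R`.

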