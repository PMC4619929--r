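#' Configuration for the synthetic multi-species generator
#'
#' Returns a validated configuration list for [generateBundle()].  The
#' defaults describe a desk-scale benchmark: 300 proteins and 40 reference
#' taxa per species, 50 planted interacting pairs per species combined with
#' negatives at 1:10, and planted signal split evenly between the
#' phylogenetic-profile channel and the GO term-sharing channel so that
#' neither base-classifier family alone sees all of it.
#'
#' @param species character vector of species codes; defaults to the seven
#'   training networks of the classifier grid.
#' @param nProteins proteins per species.
#' @param nTaxa reference taxa (shared vocabulary across species).
#' @param nPositives planted interacting pairs per species.
#' @param ratio negatives per positive in each species' gold standard.
#' @param coevolutionStrength probability in `[0, 1]` that an interacting
#'   pair's profiles agree at a taxon *beyond* the background agreement:
#'   per-taxon agreement is `background + strength * (1 - background)`.
#' @param goSharingStrength probability in `[0, 1]` that each GO term of
#'   one interacting partner is copied to the other, on top of the
#'   background annotation rate.
#' @param backgroundPresence per-taxon presence probability of a
#'   non-planted profile entry (0.5: maximally entropic background).
#' @param nTermsPerAspect synthetic GO vocabulary size per aspect (shared
#'   across species).
#' @param backgroundTermRate probability a protein carries any given term.
#' @param seed integer master seed.
#' @return named list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(species = c("HS", "MM", "SP", "SC", "AT", "EC",
                                        "DM"),
                            nProteins = 300L, nTaxa = 40L, nPositives = 50L,
                            ratio = 10L, coevolutionStrength = 0.5,
                            goSharingStrength = 0.5,
                            backgroundPresence = 0.5,
                            nTermsPerAspect = 40L,
                            backgroundTermRate = 0.05, seed = 1L) {
  cfg <- list(species = species, nProteins = as.integer(nProteins),
              nTaxa = as.integer(nTaxa), nPositives = as.integer(nPositives),
              ratio = as.integer(ratio),
              coevolutionStrength = coevolutionStrength,
              goSharingStrength = goSharingStrength,
              backgroundPresence = backgroundPresence,
              nTermsPerAspect = as.integer(nTermsPerAspect),
              backgroundTermRate = backgroundTermRate,
              seed = as.integer(seed))
  probs <- c(cfg$coevolutionStrength, cfg$goSharingStrength,
             cfg$backgroundPresence, cfg$backgroundTermRate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$nProteins < 3L || cfg$nTaxa < 1L || cfg$nPositives < 1L ||
      cfg$ratio < 1L || cfg$nTermsPerAspect < 1L) {
    stop("counts must be positive (and nProteins >= 3)")
  }
  if (cfg$nPositives > choose(cfg$nProteins, 2)) {
    stop("more positives requested than distinct pairs exist")
  }
  if (choose(cfg$nProteins, 2) - cfg$nPositives <
      cfg$ratio * cfg$nPositives) {
    stop("universe too small for the requested ratio")
  }
  structure(cfg, class = "syntheticConfig")
}

# shared synthetic GO vocabulary: disjoint ID ranges per aspect
syntheticVocabulary <- function(nTermsPerAspect) {
  list(BP = sprintf("GO:%07d", 1000000L + seq_len(nTermsPerAspect)),
       CC = sprintf("GO:%07d", 2000000L + seq_len(nTermsPerAspect)),
       MF = sprintf("GO:%07d", 3000000L + seq_len(nTermsPerAspect)))
}

generateSpeciesData <- function(config, species, seed) {
  n <- config$nProteins
  prot <- sprintf("%s_P%04d", species, seq_len(n))
  vocab <- syntheticVocabulary(config$nTermsPerAspect)

  withr::with_seed(seed, {
    # planted interacting pairs: distinct canonical pairs drawn uniformly
    idx <- combn(n, 2)
    take <- sample(ncol(idx), config$nPositives)
    pos <- canonicalizePairs(prot[idx[1L, take]], prot[idx[2L, take]])
    pos$label <- "positive"

    # profile matrix: background Bernoulli rows, then co-evolution planted
    # by regenerating one partner's row from the other's with elevated
    # per-taxon agreement
    m <- matrix(as.integer(runif(n * config$nTaxa) <
                             config$backgroundPresence),
                nrow = n,
                dimnames = list(prot, sprintf("T%03d", seq_len(config$nTaxa))))
    p0 <- config$backgroundPresence
    backgroundAgree <- p0^2 + (1 - p0)^2
    agreeProb <- backgroundAgree +
      config$coevolutionStrength * (1 - backgroundAgree)
    planted <- character(0)
    for (k in seq_len(nrow(pos))) {
      a <- pos$proteinA[k]; b <- pos$proteinB[k]
      if (a %in% planted && b %in% planted) next
      # derive the not-yet-planted partner from the other
      if (a %in% planted) { src <- a; dst <- b } else { src <- b; dst <- a }
      agree <- runif(config$nTaxa) < agreeProb
      m[dst, ] <- ifelse(agree, m[src, ], 1L - m[src, ])
      planted <- unique(c(planted, src, dst))
    }
    profiles <- new("PhyloProfiles", presence = m)

    # GO annotations: background term draws per aspect, then term sharing
    # planted within interacting pairs
    ann <- lapply(prot, function(p) {
      lapply(vocab, function(terms) {
        terms[runif(length(terms)) < config$backgroundTermRate]
      })
    })
    names(ann) <- prot
    for (k in seq_len(nrow(pos))) {
      a <- pos$proteinA[k]; b <- pos$proteinB[k]
      for (aspect in c("BP", "CC", "MF")) {
        ta <- ann[[a]][[aspect]]
        share <- ta[runif(length(ta)) < config$goSharingStrength]
        ann[[b]][[aspect]] <- sort(unique(c(ann[[b]][[aspect]], share)))
      }
    }
    annotations <- new("GOAnnotations", annotations = ann)

    gold <- suppressMessages(
      assembleGoldStandard(pos, universe = prot, ratio = config$ratio,
                           seed = deriveSeed(seed, 17L)))
    list(gold = gold, positives = pos, profiles = profiles,
         annotations = annotations)
  })
}

#' Generate a synthetic multi-species data bundle
#'
#' Produces, for every configured species, a planted interaction network
#' with its gold standard (positives plus sampled negatives), a
#' phylogenetic profile matrix with planted co-evolution between
#' interacting partners, and GO annotations with planted term sharing.
#' Species share the reference-taxa and GO-term vocabularies but have
#' disjoint protein ID spaces, mirroring the cross-species transfer
#' setting.  Deterministic for a given config seed.
#'
#' @param config list from [syntheticConfig()].
#' @return named list keyed by species code; each element has components
#'   `gold`, `positives`, `profiles`, `annotations`.  The config is
#'   attached as attribute `"config"`.
#' @export
generateBundle <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  bundle <- lapply(seq_along(config$species), function(i) {
    generateSpeciesData(config, config$species[i],
                        deriveSeed(config$seed, 100L + i))
  })
  names(bundle) <- config$species
  attr(bundle, "config") <- config
  bundle
}

#' Write a synthetic bundle to disk
#'
#' Emits, per species, the exact external formats the loaders read: the
#' positive pair TSV (`<sp>_positives.tsv`), the gold-standard TSV
#' (`<sp>_gold.tsv`), the profile matrix TSV (`<sp>_profiles.tsv`) and a
#' GAF 2.2 annotation file (`<sp>_annotations.gaf`).  Proteins with no GO
#' terms at all have no GAF lines, which is the one piece of in-memory
#' state the formats cannot carry.
#'
#' @param bundle list from [generateBundle()].
#' @param dir output directory (created if needed).
#' @return invisibly, a character vector of the written paths.
#' @export
writeBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sp in names(bundle)) {
    b <- bundle[[sp]]
    posPath <- file.path(dir, paste0(sp, "_positives.tsv"))
    write.table(b$positives[, c("proteinA", "proteinB")], posPath,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    goldPath <- file.path(dir, paste0(sp, "_gold.tsv"))
    writeGoldStandard(b$gold, goldPath)
    profPath <- file.path(dir, paste0(sp, "_profiles.tsv"))
    writeProfiles(b$profiles, profPath)
    gafPath <- file.path(dir, paste0(sp, "_annotations.gaf"))
    writeAnnotations(b$annotations, gafPath, db = sp)
    paths <- c(paths, posPath, goldPath, profPath, gafPath)
  }
  invisible(paths)
}
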