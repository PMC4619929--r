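# Reference-taxa selection strategies.
#
# Each strategy maps a profile matrix (and, for the supervised ones, a
# labelled training pair set) to a non-empty subset of taxon IDs over which
# the pair scorers operate.  Supervised strategies search for subsets that
# maximize the training AUC of the co-occurrence (pp) scorer; randomized
# strategies draw from taxa in sorted-name order so that the result depends
# only on the seed and the taxon set, not on column order.

taxaStrategyNames <- c("identity", "random_subset", "redundancy_filter",
                       "tree_level_filter", "greedy_forward",
                       "greedy_backward", "genetic_algorithm",
                       "simulated_annealing")

supervisedStrategies <- c("greedy_forward", "greedy_backward",
                          "genetic_algorithm", "simulated_annealing")

#' Registered reference-taxa selection strategies
#'
#' @return character vector of the eight registered strategy names.
#' @export
taxaStrategies <- function() taxaStrategyNames

# Per-pair mismatch matrix (pairs x taxa) and labels for supervised search.
# pp score over a taxon subset S is 1 - rowMeans(D[, S]).
pairMismatch <- function(profiles, trainingPairs) {
  A <- profileRows(profiles, trainingPairs$proteinA)
  B <- profileRows(profiles, trainingPairs$proteinB)
  D <- (A != B) * 1
  colnames(D) <- taxa(profiles)
  D
}

subsetAUC <- function(D, pos, cols) {
  s <- if (length(cols) == 1L) 1 - D[, cols] else 1 - rowMeans(D[, cols, drop = FALSE])
  nPos <- sum(pos); nNeg <- length(pos) - nPos
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Select reference taxa
#'
#' Applies one of the eight registered taxa-selection strategies to a
#' profile matrix.  Unsupervised strategies (`identity`, `random_subset`,
#' `redundancy_filter`, `tree_level_filter`) use the matrix alone;
#' supervised strategies (`greedy_forward`, `greedy_backward`,
#' `genetic_algorithm`, `simulated_annealing`) additionally require a
#' labelled training pair set and search for taxa that maximize the
#' training AUC of the co-occurrence scorer.  Deterministic for a given
#' seed; always returns a non-empty taxon subset.
#'
#' @param profiles [PhyloProfiles-class] object.
#' @param strategy one of [taxaStrategies()].
#' @param params named list of strategy parameters (see Details).
#' @param seed integer RNG seed for randomized strategies.
#' @param trainingPairs data.frame with `proteinA`, `proteinB`, `label`
#'   (required for supervised strategies).
#' @return character vector of selected taxon IDs.
#'
#' @details Strategy parameters (all optional):
#' * `random_subset`: `fraction` of taxa to keep (default 0.5).
#' * `redundancy_filter`: `threshold` absolute correlation above which a
#'   taxon column is considered redundant (default 0.95).
#' * `tree_level_filter`: `k` clusters to cut the taxon dendrogram into
#'   (default `max(2, floor(M/4))`); one medoid taxon kept per cluster.
#' * `greedy_forward` / `greedy_backward`: `maxTaxa` / `minTaxa` bounds on
#'   the search (defaults 10 and 2).
#' * `genetic_algorithm`: `popSize` (20), `generations` (12),
#'   `mutationRate` (1/M).
#' * `simulated_annealing`: `iterations` (200), `temp0` (0.05).
#' @export
selectTaxa <- function(profiles, strategy, params = list(), seed = 1L,
                       trainingPairs = NULL) {
  if (!strategy %in% taxaStrategyNames) {
    stop("unknown taxa strategy: ", strategy)
  }
  if (strategy %in% supervisedStrategies && is.null(trainingPairs)) {
    stop("strategy '", strategy, "' requires labelled training pairs")
  }
  m <- profileMatrix(profiles)
  allTaxa <- sort(colnames(m))
  sel <- switch(strategy,
    identity = colnames(m),
    random_subset = {
      frac <- params$fraction %||% 0.5
      k <- max(2L, min(length(allTaxa), round(frac * length(allTaxa))))
      withr::with_seed(seed, sort(sample(allTaxa, k)))
    },
    redundancy_filter = redundancyFilter(m, params$threshold %||% 0.95),
    tree_level_filter = treeLevelFilter(m, params$k),
    greedy_forward = greedySearch(profiles, trainingPairs, forward = TRUE,
                                  maxTaxa = params$maxTaxa %||% 10L),
    greedy_backward = greedySearch(profiles, trainingPairs, forward = FALSE,
                                   minTaxa = params$minTaxa %||% 2L),
    genetic_algorithm = gaSearch(profiles, trainingPairs, seed,
                                 popSize = params$popSize %||% 20L,
                                 generations = params$generations %||% 12L,
                                 mutationRate = params$mutationRate),
    simulated_annealing = saSearch(profiles, trainingPairs, seed,
                                   iterations = params$iterations %||% 200L,
                                   temp0 = params$temp0 %||% 0.05)
  )
  if (length(sel) == 0L) sel <- colnames(m)
  sel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drop taxon columns nearly collinear with an already-kept column.
# Columns are visited in sorted-name order so the result is column-order
# invariant; constant columns are compared by equality.
redundancyFilter <- function(m, threshold) {
  ord <- sort(colnames(m))
  kept <- character(0)
  for (tx in ord) {
    redundant <- FALSE
    for (kx in kept) {
      x <- m[, tx]; y <- m[, kx]
      r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        as.numeric(all(x == y) || all(x == 1 - y))
      } else {
        abs(cor(x, y))
      }
      if (r >= threshold) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, tx)
  }
  kept
}

# Cluster taxa by profile dissimilarity and keep one medoid per cluster,
# emulating a tree-level cut over the reference-taxa hierarchy.
treeLevelFilter <- function(m, k = NULL) {
  M <- ncol(m)
  if (is.null(k)) k <- max(2L, floor(M / 4))
  k <- min(k, M)
  m <- m[, sort(colnames(m)), drop = FALSE]
  d <- dist(t(m), method = "manhattan")
  grp <- cutree(hclust(d, method = "average"), k = k)
  dm <- as.matrix(d)
  vapply(split(names(grp), grp), function(members) {
    sub <- dm[members, members, drop = FALSE]
    members[which.min(rowSums(sub))]
  }, character(1), USE.NAMES = FALSE)
}

greedySearch <- function(profiles, trainingPairs, forward, maxTaxa = 10L,
                         minTaxa = 2L) {
  D <- pairMismatch(profiles, trainingPairs)
  pos <- asPositiveLogical(trainingPairs$label)
  allTaxa <- sort(colnames(D))
  if (forward) {
    current <- character(0)
    bestAUC <- -Inf
    while (length(current) < min(maxTaxa, length(allTaxa))) {
      cand <- setdiff(allTaxa, current)
      aucs <- vapply(cand, function(tx) subsetAUC(D, pos, c(current, tx)),
                     numeric(1))
      best <- which.max(aucs)
      if (aucs[best] <= bestAUC + 1e-12 && length(current) > 0L) break
      bestAUC <- aucs[best]
      current <- c(current, cand[best])
    }
    sort(current)
  } else {
    current <- allTaxa
    bestAUC <- subsetAUC(D, pos, current)
    while (length(current) > minTaxa) {
      aucs <- vapply(current, function(tx) {
        subsetAUC(D, pos, setdiff(current, tx))
      }, numeric(1))
      best <- which.max(aucs)
      if (aucs[best] < bestAUC - 1e-12) break
      bestAUC <- aucs[best]
      current <- setdiff(current, current[best])
    }
    sort(current)
  }
}

gaSearch <- function(profiles, trainingPairs, seed, popSize, generations,
                     mutationRate = NULL) {
  D <- pairMismatch(profiles, trainingPairs)
  pos <- asPositiveLogical(trainingPairs$label)
  allTaxa <- sort(colnames(D))
  M <- length(allTaxa)
  if (is.null(mutationRate)) mutationRate <- 1 / M
  fitness <- function(bits) {
    if (!any(bits)) return(0)
    subsetAUC(D, pos, allTaxa[bits])
  }
  withr::with_seed(seed, {
    pop <- replicate(popSize, runif(M) < 0.5, simplify = FALSE)
    pop <- lapply(pop, function(b) { if (!any(b)) b[sample.int(M, 1)] <- TRUE; b })
    fit <- vapply(pop, fitness, numeric(1))
    for (g in seq_len(generations)) {
      newPop <- vector("list", popSize)
      newPop[[1L]] <- pop[[which.max(fit)]]  # elitism
      for (i in 2:popSize) {
        # binary tournament selection for both parents
        pick <- function() {
          c2 <- sample.int(popSize, 2L)
          pop[[c2[which.max(fit[c2])]]]
        }
        p1 <- pick(); p2 <- pick()
        cross <- runif(M) < 0.5
        child <- ifelse(cross, p1, p2)
        flip <- runif(M) < mutationRate
        child[flip] <- !child[flip]
        if (!any(child)) child[sample.int(M, 1)] <- TRUE
        newPop[[i]] <- child
      }
      pop <- newPop
      fit <- vapply(pop, fitness, numeric(1))
    }
    sort(allTaxa[pop[[which.max(fit)]]])
  })
}

saSearch <- function(profiles, trainingPairs, seed, iterations, temp0) {
  D <- pairMismatch(profiles, trainingPairs)
  pos <- asPositiveLogical(trainingPairs$label)
  allTaxa <- sort(colnames(D))
  M <- length(allTaxa)
  withr::with_seed(seed, {
    state <- runif(M) < 0.5
    if (!any(state)) state[sample.int(M, 1)] <- TRUE
    evalState <- function(b) if (any(b)) subsetAUC(D, pos, allTaxa[b]) else 0
    cur <- evalState(state)
    best <- state; bestVal <- cur
    for (it in seq_len(iterations)) {
      temp <- temp0 * (1 - (it - 1) / iterations)
      cand <- state
      j <- sample.int(M, 1L)
      cand[j] <- !cand[j]
      if (!any(cand)) next
      val <- evalState(cand)
      if (val >= cur || runif(1) < exp((val - cur) / max(temp, 1e-8))) {
        state <- cand; cur <- val
        if (cur > bestVal) { best <- state; bestVal <- cur }
      }
    }
    sort(allTaxa[best])
  })
}
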