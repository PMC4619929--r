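#' Load a phylogenetic profile matrix from TSV
#'
#' Expects a header row `protein<TAB>taxon1...taxonM` followed by one row
#' per protein with 0/1 presence calls.  Any non-binary cell is rejected
#' with its row and column named; ragged rows and duplicate protein or
#' taxon IDs are errors.  All-zero protein rows are permitted but reported.
#'
#' @param path path to the profile TSV.
#' @return [PhyloProfiles-class] object.
#' @export
loadProfiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2L) stop("empty profile file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) stop("header must list at least one taxon")
  taxaIds <- header[-1L]
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header))) {
    stop("ragged row at line ", which(nf != length(header))[1] + 1L)
  }
  prot <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(prot)) {
    stop("duplicate protein ID: ", prot[duplicated(prot)][1])
  }
  if (anyDuplicated(taxaIds)) {
    stop("duplicate taxon ID: ", taxaIds[duplicated(taxaIds)][1])
  }
  cells <- vapply(body, function(f) f[-1L], character(length(taxaIds)))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1L) else t(cells)
  bad <- which(matrix(!(cells %in% c("0", "1")), nrow = nrow(cells)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-binary cell '", cells[bad[1, 1], bad[1, 2]], "' at protein ",
         prot[bad[1, 1]], ", taxon ", taxaIds[bad[1, 2]])
  }
  m <- matrix(as.integer(cells), nrow = length(prot),
              dimnames = list(prot, taxaIds))
  nZero <- sum(rowSums(m) == 0L)
  if (nZero > 0L) message(nZero, " all-zero profile rows")
  new("PhyloProfiles", presence = m)
}

#' Write a profile matrix to TSV
#'
#' @param profiles [PhyloProfiles-class] object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeProfiles <- function(profiles, path) {
  m <- profileMatrix(profiles)
  out <- data.frame(protein = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

profileRows <- function(profiles, ids, selected = NULL) {
  m <- profileMatrix(profiles)
  missing <- setdiff(unique(ids), rownames(m))
  if (length(missing)) {
    stop("unknown protein ID: ", paste(head(missing, 3), collapse = ", "))
  }
  if (!is.null(selected)) {
    bad <- setdiff(selected, colnames(m))
    if (length(bad)) stop("unknown taxon in selection: ", bad[1])
    m <- m[, selected, drop = FALSE]
  }
  m[ids, , drop = FALSE]
}

#' Profile co-occurrence score of a protein pair
#'
#' Normalized Hamming similarity of the two presence/absence rows over the
#' selected reference taxa: `1 - (number of mismatching taxa) / (number of
#' taxa)`.  Identical profiles score 1, complementary profiles score 0.
#'
#' @param profiles [PhyloProfiles-class] object.
#' @param a,b protein IDs.
#' @param selected optional taxon-ID subset (default: all taxa).
#' @return similarity in `[0, 1]`.
#' @export
scorePP <- function(profiles, a, b, selected = NULL) {
  scoreProfilePairs(profiles, data.frame(proteinA = a, proteinB = b),
                    method = "pp", selected = selected)[1L]
}

#' Mutual information of two phylogenetic profiles
#'
#' Plug-in mutual information (base 2) of the two binary presence rows
#' across the selected taxa, with the `0 * log 0 = 0` convention.  A
#' constant row has zero entropy and therefore zero mutual information.
#'
#' @inheritParams scorePP
#' @return mutual information in bits (>= 0).
#' @export
scoreMI <- function(profiles, a, b, selected = NULL) {
  scoreProfilePairs(profiles, data.frame(proteinA = a, proteinB = b),
                    method = "mi", selected = selected)[1L]
}

#' Hypergeometric co-occurrence score of a protein pair
#'
#' Upper-tail hypergeometric test of profile co-occurrence: with N selected
#' taxa, K presences for protein a, n presences for protein b and k taxa
#' where both are present, returns `-log10 P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.  `k = 0` gives 0 since `P(X >= 0) = 1`;
#' larger values mean more co-occurrence than expected by chance.
#'
#' @inheritParams scorePP
#' @return `-log10` upper-tail p-value (>= 0).
#' @export
scoreHypergeom <- function(profiles, a, b, selected = NULL) {
  scoreProfilePairs(profiles, data.frame(proteinA = a, proteinB = b),
                    method = "hg", selected = selected)[1L]
}

#' Score many pairs against one profile matrix
#'
#' Vectorized scorer used by the classifier grid: computes the
#' co-occurrence (`"pp"`), mutual-information (`"mi"`) or hypergeometric
#' (`"hg"`) score for every pair in one call.
#'
#' @param profiles [PhyloProfiles-class] object.
#' @param pairs data.frame with columns `proteinA`, `proteinB`.
#' @param method `"pp"`, `"mi"` or `"hg"`.
#' @param selected optional taxon-ID subset (default: all taxa).
#' @return numeric vector of scores, one per pair.
#' @export
scoreProfilePairs <- function(profiles, pairs, method = c("pp", "mi", "hg"),
                              selected = NULL) {
  method <- match.arg(method)
  A <- profileRows(profiles, pairs$proteinA, selected)
  B <- profileRows(profiles, pairs$proteinB, selected)
  N <- ncol(A)
  if (N < 1L) stop("at least one selected taxon required")
  n11 <- unname(rowSums(A & B))
  n10 <- unname(rowSums(A & !B))
  n01 <- unname(rowSums(!A & B))
  n00 <- N - n11 - n10 - n01
  switch(method,
    pp = 1 - (n10 + n01) / N,
    mi = {
      plogp <- function(p, q) ifelse(p > 0, p * log2(p / q), 0)
      pa <- (n11 + n10) / N
      pb <- (n11 + n01) / N
      mi <- plogp(n11 / N, pa * pb) +
            plogp(n10 / N, pa * (1 - pb)) +
            plogp(n01 / N, (1 - pa) * pb) +
            plogp(n00 / N, (1 - pa) * (1 - pb))
      pmax(mi, 0)
    },
    hg = {
      K <- n11 + n10
      nB <- n11 + n01
      p <- phyper(n11 - 1, K, N - K, nB, lower.tail = FALSE)
      pmax(-log10(p), 0)
    }
  )
}
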