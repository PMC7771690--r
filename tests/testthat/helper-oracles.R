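# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: alignment is re-done with a hand-written Gotoh
# DP, clade sets come from ape::prop.part, distances from igraph.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomAA <- function(len) paste(sample(AA20, len, replace = TRUE),
                                collapse = "")

# Smith-Waterman local alignment score by full dynamic programming with
# affine gaps costing open + (k - 1) * ext for a gap of length k.
oracleLocalScore <- function(a, b, open = 8, ext = 8,
                             submat = "BLOSUM50") {
  e <- new.env(); utils::data(list = submat, package = "Biostrings", envir = e)
  S <- get(submat, envir = e)
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- M[, 1] <- -Inf
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # indices offset by one: row i+1 / col j+1 hold prefix lengths (i, j)
      M[i + 1, j + 1] <- S[a[i], b[j]] + max(0, M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open, Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

oracleNormalizedSW <- function(a, b, open = 8, ext = 8) {
  oracleLocalScore(a, b, open, ext) / oracleLocalScore(a, a, open, ext)
}

# Jaccard index by explicit set arithmetic over reaction id sets.
oracleJaccard <- function(m, orgA, orgB) {
  p <- presence(m)
  A <- colnames(p)[p[orgA, ] == 1]
  B <- colnames(p)[p[orgB, ] == 1]
  length(intersect(A, B)) / length(union(A, B))
}

# Sorted leaf-label set of every internal clade, via ape::prop.part.
oracleCladeSets <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, function(idx) sort(attr(pp, "labels")[idx]))
}

oracleCladeKeys <- function(tree)
  sort(vapply(oracleCladeSets(tree), paste, character(1), collapse = "\r"))

# Distance-weighted leaf-neighborhood similarity recomputed independently:
# igraph shortest paths for leaf-to-node edge counts, prop.part for clades.
oracleWeightedSimilarity <- function(tA, tB) {
  ntip <- length(tA$tip.label)
  g <- igraph::graph_from_edgelist(tA$edge, directed = FALSE)
  dmat <- igraph::distances(g)
  setsA <- oracleCladeSets(tA)
  keysB <- vapply(oracleCladeSets(tB), paste, character(1), collapse = "\r")
  nodeIds <- (ntip + 1):(2 * ntip - 1)
  keyA <- vapply(setsA, paste, character(1), collapse = "\r")
  minA <- vapply(setsA, `[`, character(1), 1)
  sizeA <- lengths(setsA)
  perLeaf <- vapply(seq_len(ntip), function(tip) {
    ord <- order(dmat[tip, nodeIds], minA, sizeA)
    match_ <- (keyA %in% keysB)[ord]
    w <- (ntip - seq_len(ntip - 1)) / (ntip - 1)
    (2 / ntip) * sum(w * match_)
  }, numeric(1))
  mean(perLeaf)
}

# Random rooted binary tree with branch lengths, canonical labels t1..tn.
randomTree <- function(ntip) {
  tree <- ape::rtree(ntip, rooted = TRUE)
  tree$tip.label <- sample(paste0("t", seq_len(ntip)))
  tree
}

# Re-orders children randomly without changing the topology.
shuffleChildOrder <- function(tree) {
  nodes <- unique(tree$edge[, 1])
  for (nd in sample(nodes, max(1, length(nodes) %/% 2)))
    tree <- ape::rotate(tree, nd)
  tree
}

# Two-clade fixture with terminal cherries used by the acceptance suite:
# 20 organisms in two clades of five cherries each.
acceptanceCladeSpec <- function(seed = 1L, subProb = 0.05) {
  pairs <- function(pfx) lapply(seq(1, 9, 2),
                                function(i) sprintf("%s%02d", pfx, c(i, i + 1)))
  cladeSpec(list(pairs("a"), pairs("b")), seed = seed, subProb = subProb)
}
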