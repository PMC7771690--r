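#' @include treebuild.R
NULL

# Leaf-label set under every node; list indexed by node id, each sorted.
.nodeLeafSets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  # postorder guarantees children are filled before their parent
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; c <- edges[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  lapply(sets, sort)
}

.setKey <- function(labels) paste(labels, collapse = "\r")

.checkLeafSets <- function(tA, tB) {
  a <- sort(tA$tip.label); b <- sort(tB$tip.label)
  if (!identical(a, b)) {
    diff <- c(setdiff(a, b), setdiff(b, a))
    stop("trees have different leaf sets; symmetric difference: ",
         paste(diff, collapse = ", "))
  }
}

# key of the parent clade (leaf set of the leaf's parent node) per leaf
.parentCladeKeys <- function(tree, sets) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip)
  parent[tree$edge[tree$edge[, 2L] <= ntip, 2L]] <-
    tree$edge[tree$edge[, 2L] <= ntip, 1L]
  keys <- vapply(seq_len(ntip), function(i) .setKey(sets[[parent[i]]]),
                 character(1))
  setNames(keys, tree$tip.label)
}

#' Binary leaf-neighborhood tree similarity
#'
#' For each leaf, the per-leaf score F is 1 exactly when the leaf set of the
#' leaf's parent clade (the smallest clade containing it) is identical in
#' both trees, and 0 otherwise; K is the mean of F over the N leaves. K = 1
#' for identical topologies, and child order never matters (both trees are
#' canonicalized implicitly through leaf-set comparison).
#'
#' @param tA,tB rooted \code{phylo} trees over the same leaf set.
#' @return a [TreeSimilarityResult-class] with mode "binary".
#' @examples
#' tA <- newickToTree("((A:1,B:1):1,(C:1,D:1):1);")
#' tB <- newickToTree("((A:1,C:1):1,(B:1,D:1):1);")
#' treeSimilarityK(binaryTreeSimilarity(tA, tB))
#' @export
binaryTreeSimilarity <- function(tA, tB) {
  .checkLeafSets(tA, tB)
  keysA <- .parentCladeKeys(tA, .nodeLeafSets(tA))
  keysB <- .parentCladeKeys(tB, .nodeLeafSets(tB))
  leaves <- sort(tA$tip.label)
  f <- as.numeric(keysA[leaves] == keysB[leaves])
  names(f) <- leaves
  new("TreeSimilarityResult", K = mean(f), perLeaf = f, mode = "binary")
}

# Edge-count distance from each tip to every node (undirected BFS).
.tipNodeDistances <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    adj[[p]] <- c(adj[[p]], c)
    adj[[c]] <- c(adj[[c]], p)
  }
  dist <- matrix(NA_integer_, ntip, nn)
  for (tip in seq_len(ntip)) {
    d <- rep(NA_integer_, nn)
    d[tip] <- 0L
    queue <- tip
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(d[w])) {
        d[w] <- d[v] + 1L
        queue <- c(queue, w)
      }
    }
    dist[tip, ] <- d
  }
  dist
}

#' Distance-weighted leaf-neighborhood tree similarity
#'
#' Graded variant of [binaryTreeSimilarity()]: for each leaf, the N - 1
#' internal clades of the first tree are enumerated in increasing
#' topological distance (edge count) from the leaf, ties broken by the
#' clades' smallest leaf label and then size. The eta-th clade scores 1 when
#' its leaf set occurs as a clade anywhere in the second tree, weighted by
#' (N - eta)/(N - 1), so mismatches near the leaf cost the most; with four
#' organisms the weights are 3/3, 2/3, 1/3. The per-leaf score is
#' F = (2/N) * sum_eta w_eta * match_eta, which equals 1 when every clade
#' matches, and K is the mean over leaves.
#'
#' @param tA,tB rooted binary \code{phylo} trees over the same leaf set.
#' @return a [TreeSimilarityResult-class] with mode "weighted".
#' @export
weightedTreeSimilarity <- function(tA, tB) {
  .checkLeafSets(tA, tB)
  ntip <- length(tA$tip.label)
  if (ntip < 2L) stop("at least two leaves are required")
  if (tA$Nnode != ntip - 1L || tB$Nnode != ntip - 1L)
    stop("weighted similarity requires binary trees (N - 1 internal nodes)")
  setsA <- .nodeLeafSets(tA)
  setsB <- .nodeLeafSets(tB)
  keysB <- vapply(setsB[(ntip + 1L):(2L * ntip - 1L)], .setKey, character(1))
  internal <- (ntip + 1L):(2L * ntip - 1L)
  keysA <- vapply(setsA[internal], .setKey, character(1))
  minA <- vapply(setsA[internal], `[`, character(1), 1L)
  sizeA <- lengths(setsA[internal])
  matchA <- keysA %in% keysB
  dist <- .tipNodeDistances(tA)

  weights <- (ntip - seq_len(ntip - 1L)) / (ntip - 1L)
  f <- vapply(seq_len(ntip), function(tip) {
    ord <- order(dist[tip, internal], minA, sizeA)
    (2 / ntip) * sum(weights * matchA[ord])
  }, numeric(1))
  leaves <- tA$tip.label
  names(f) <- leaves
  f <- f[sort(leaves)]
  new("TreeSimilarityResult", K = mean(f), perLeaf = f, mode = "weighted")
}
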