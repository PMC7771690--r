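#' @include AllClasses.R
NULL

#' Convert a similarity matrix to a distance matrix
#'
#' Elementwise d = 1 - s with the diagonal forced to zero. Similarities in
#' [0, 1] map to distances in [0, 1]; negative similarities (possible with
#' negative penalty scores) map to distances above 1, which UPGMA handles
#' without modification.
#'
#' @param s a [SimilarityMatrix-class] or a symmetric numeric matrix with
#'   dimnames.
#' @return numeric distance matrix with zero diagonal.
#' @examples
#' similarityToDistance(pairwiseJaccard(table5Fixture()$orgMatrix))
#' @export
similarityToDistance <- function(s) {
  v <- if (is(s, "SimilarityMatrix")) s@values else as.matrix(s)
  if (!isSymmetric(unname(v), tol = 1e-12))
    stop("similarity matrix must be symmetric")
  d <- 1 - v
  diag(d) <- 0
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair group method with arithmetic mean: repeatedly
#' merge the closest pair of clusters; the distance from a merged cluster to
#' any other is the size-weighted average of its members' distances, and the
#' merge node sits at height (merge distance)/2, so the tree is ultrametric.
#' Ties are resolved deterministically: among all pairs at the minimal
#' distance, the pair whose (smallest-leaf-label, smallest-leaf-label) pair
#' is lexicographically smallest is merged first, so equal-distance merges
#' always happen sequentially and the output is binary and reproducible
#' across platforms.
#'
#' @param d symmetric numeric distance matrix with zero diagonal and
#'   organism dimnames; N >= 2.
#' @return a rooted ultrametric \code{phylo} tree (ape) in canonical
#'   leaf-sorted child order.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' treeToNewick(upgmaTree(d))
#' @export
upgmaTree <- function(d) {
  d <- as.matrix(d)
  if (any(is.na(d))) stop("NaN/NA in distance matrix")
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix must have unique rownames")
  n <- nrow(d)
  if (n < 2L) stop("at least two organisms are required")

  nodes <- as.list(labels)              # newick fragments under construction
  heights <- numeric(n)
  sizes <- rep(1L, n)
  mins <- labels                        # smallest leaf label per cluster
  D <- d
  active <- seq_len(n)
  while (length(active) > 1L) {
    sub <- D[active, active, drop = FALSE]
    off <- sub[upper.tri(sub)]
    dmin <- min(off)
    # averaging erodes exact ties by ~1 ulp; treat near-equal distances as
    # tied so the deterministic label-based tie-break still applies
    tol <- 1e-12 * max(abs(dmin), 1)
    idx <- which(sub <= dmin + tol & upper.tri(sub), arr.ind = TRUE)
    # deterministic tie-break on the clusters' smallest leaf labels
    lo <- pmin(mins[active[idx[, 1L]]], mins[active[idx[, 2L]]])
    hi <- pmax(mins[active[idx[, 1L]]], mins[active[idx[, 2L]]])
    pick <- order(lo, hi)[1L]
    i <- active[idx[pick, 1L]]
    j <- active[idx[pick, 2L]]

    h <- dmin / 2
    newickChild <- function(k) {
      frag <- nodes[[k]]
      sprintf("%s:%s", frag, format(h - heights[k], digits = 15))
    }
    ord <- if (mins[i] <= mins[j]) c(i, j) else c(j, i)
    merged <- sprintf("(%s,%s)", newickChild(ord[1L]), newickChild(ord[2L]))

    rest <- setdiff(active, c(i, j))
    newD <- (sizes[i] * D[i, rest] + sizes[j] * D[j, rest]) /
      (sizes[i] + sizes[j])
    D[i, rest] <- newD
    D[rest, i] <- newD
    nodes[[i]] <- merged
    heights[i] <- h
    sizes[i] <- sizes[i] + sizes[j]
    mins[i] <- min(mins[i], mins[j])
    active <- setdiff(active, j)
  }
  tree <- ape::read.tree(text = paste0(nodes[[active]], ";"))
  canonicalizeTree(tree)
}

# children edge indices per internal node, keyed by node id as character
.childEdges <- function(tree) {
  split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
}

# Recursive canonical newick; returns list(str, minLeaf) per node.
.canonicalFragment <- function(tree, node, kids, lengths) {
  ntip <- length(tree$tip.label)
  if (node <= ntip)
    return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
  edges <- kids[[as.character(node)]]
  parts <- lapply(edges, function(e) {
    child <- .canonicalFragment(tree, tree$edge[e, 2L], kids, lengths)
    str <- if (is.null(lengths)) child$str else
      sprintf("%s:%s", child$str, format(lengths[e], digits = 15))
    list(str = str, min = child$min)
  })
  ord <- order(vapply(parts, `[[`, character(1), "min"))
  list(str = sprintf("(%s)", paste(vapply(parts[ord], `[[`, character(1),
                                          "str"), collapse = ",")),
       min = min(vapply(parts, `[[`, character(1), "min")))
}

#' Canonicalize a rooted tree
#'
#' Reorders the children of every node by the smallest leaf label contained
#' beneath them, yielding a unique representation per topology (mirror-image
#' trees become identical). Idempotent; branch lengths are preserved.
#'
#' @param tree a rooted \code{phylo} tree with unique leaf labels.
#' @return the canonical \code{phylo} tree.
#' @export
canonicalizeTree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  kids <- .childEdges(tree)
  root <- length(tree$tip.label) + 1L
  frag <- .canonicalFragment(tree, root, kids, tree$edge.length)
  ape::read.tree(text = paste0(frag$str, ";"))
}

#' Serialize a tree as Newick
#'
#' The tree is canonicalized first so equal topologies always serialize
#' identically. Round trips through [newickToTree()] preserve topology and
#' branch lengths to well below 1e-9.
#'
#' @param tree a rooted \code{phylo} tree.
#' @param path optional output file; when given the Newick string is also
#'   written there.
#' @return the Newick string.
#' @export
treeToNewick <- function(tree, path = NULL) {
  frag <- {
    t2 <- canonicalizeTree(tree)
    kids <- .childEdges(t2)
    .canonicalFragment(t2, length(t2$tip.label) + 1L, kids, t2$edge.length)
  }
  nw <- paste0(frag$str, ";")
  if (!is.null(path)) writeLines(nw, path)
  nw
}

#' Parse a Newick tree
#'
#' Accepts either a Newick string or a path to a Newick file; the parsed
#' tree is returned in canonical child order. Unbalanced parentheses are
#' reported with their character position.
#'
#' @param x Newick text (anything containing \code{"("}) or a file path.
#' @return a canonical \code{phylo} tree.
#' @export
newickToTree <- function(x) {
  text <- if (grepl("(", x[1L], fixed = TRUE)) x[1L] else
    paste(readLines(x), collapse = "")
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("malformed Newick: unbalanced ')' at position %d", k))
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input", depth))
  tree <- tryCatch(ape::read.tree(text = text), error = function(e)
    stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  if (anyDuplicated(tree$tip.label))
    stop("leaf labels must be unique")
  canonicalizeTree(tree)
}
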