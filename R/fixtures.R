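#' @include AllClasses.R treebuild.R
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Two-organism worked-example fixture
#'
#' The 2 x 11 binary presence matrix for organisms A and B used throughout
#' the worked examples, together with its per-reaction alignment score row:
#' four shared reactions score 0.87, 0.93, 0.75 and 0.89, four reactions are
#' present in exactly one organism (status ONE_SIDED), and three are absent
#' from both (status ABSENT_BOTH, never contributing to the average).
#' J(A, B) = 4/8 = 0.5 on this matrix.
#'
#' @return list with \code{orgMatrix} (an [OrgMatrix-class]) and
#'   \code{scoreTable} (data.frame: reaction, status, score) ready for
#'   [averageSimilarity()].
#' @examples
#' fx <- table5Fixture()
#' rowSums(presence(fx$orgMatrix))
#' averageSimilarity(fx$scoreTable, penalty = 0)
#' @export
table5Fixture <- function() {
  rxns <- sprintf("R%02d", 1:11)
  pres <- rbind(
    A = c(1, 1, 0, 0, 1, 1, 1, 1, 0, 0, 1),
    B = c(1, 0, 0, 0, 0, 1, 1, 0, 0, 1, 1))
  colnames(pres) <- rxns
  scores <- c(0.87, NA, NA, NA, NA, 0.93, 0.75, NA, NA, NA, 0.89)
  status <- ifelse(pres["A", ] + pres["B", ] == 2L, "SHARED",
                   ifelse(pres["A", ] + pres["B", ] == 1L, "ONE_SIDED",
                          "ABSENT_BOTH"))
  list(orgMatrix = orgMatrix(pres),
       scoreTable = data.frame(reaction = rxns, status = unname(status),
                               score = scores, stringsAsFactors = FALSE))
}

#' Worked-example enzyme score matrix
#'
#' The 3 x 4 all-against-all normalized alignment score matrix for a
#' reaction catalyzed by three enzymes in organism A and four in organism B.
#' Its max aggregation ([aggregateEnzymeScores()]) is 0.87.
#'
#' @return numeric 3 x 4 matrix (rows A1..A3, columns B1..B4).
#' @examples
#' aggregateEnzymeScores(table6Fixture())
#' @export
table6Fixture <- function() {
  matrix(c(0.87, 0.48, 0.81, 0.83,
           0.65, 0.55, 0.23, 0.78,
           0.78, 0.69, 0.55, 0.62),
         nrow = 3, byrow = TRUE,
         dimnames = list(paste0("A", 1:3), paste0("B", 1:4)))
}

# depth-first walk collecting each grouping of the clade tree with a path id
.cladeNodes <- function(clades, path = character()) {
  out <- list()
  for (i in seq_along(clades)) {
    p <- c(path, as.character(i))
    cl <- clades[[i]]
    orgs <- if (is.list(cl)) .cladeOrganisms(cl) else cl
    out[[paste(p, collapse = ".")]] <- orgs
    if (is.list(cl))
      out <- c(out, .cladeNodes(cl, p))
  }
  out
}

#' Generate a clade-structured presence matrix
#'
#' Builds an organism-reaction presence matrix with planted penetration
#' strata: core reactions present in every organism (high penetration),
#' clade reactions present in exactly the members of each grouping of the
#' clade tree (medium penetration at balanced clade sizes), and private
#' reactions present in a single organism each (low penetration). Reaction
#' ids encode their stratum (\code{CORE...}, \code{CLADE_<path>_...},
#' \code{PRIV_<org>_...}) so tests can predict penetration classes exactly
#' from the spec. The matrix is fully determined by the spec.
#'
#' @param spec a [CladeSpec-class].
#' @return an [OrgMatrix-class].
#' @examples
#' m <- generateCladeMatrix(cladeSpec(list(paste0("a0", 1:4), paste0("b0", 1:4))))
#' dim(presence(m))
#' @export
generateCladeMatrix <- function(spec) {
  stopifnot(is(spec, "CladeSpec"))
  orgs <- .cladeOrganisms(spec@clades)
  nodes <- .cladeNodes(spec@clades)

  cols <- character(); blocks <- list()
  if (spec@coreReactions > 0L) {
    ids <- sprintf("CORE%03d", seq_len(spec@coreReactions))
    cols <- c(cols, ids)
    blocks <- c(blocks, lapply(ids, function(i) orgs))
  }
  if (spec@cladeReactions > 0L) {
    for (path in names(nodes)) {
      ids <- sprintf("CLADE_%s_%03d", path, seq_len(spec@cladeReactions))
      cols <- c(cols, ids)
      blocks <- c(blocks, lapply(ids, function(i) nodes[[path]]))
    }
  }
  if (spec@privateReactions > 0L) {
    for (org in orgs) {
      ids <- sprintf("PRIV_%s_%03d", org, seq_len(spec@privateReactions))
      cols <- c(cols, ids)
      blocks <- c(blocks, lapply(ids, function(i) org))
    }
  }
  p <- matrix(0L, length(orgs), length(cols), dimnames = list(orgs, cols))
  for (k in seq_along(cols))
    p[blocks[[k]], cols[k]] <- 1L
  orgMatrix(p)
}

# mutate each site independently with probability prob, uniform over the 19
# alternative residues
.mutateSeq <- function(seqChars, prob) {
  if (prob <= 0) return(seqChars)
  hit <- which(stats::runif(length(seqChars)) < prob)
  for (k in hit) {
    alt <- .AA20[.AA20 != seqChars[k]]
    seqChars[k] <- alt[sample.int(19L, 1L)]
  }
  seqChars
}

#' Attach clade-correlated synthetic enzyme sequences
#'
#' For every catalog reaction one root sequence is drawn uniformly over the
#' 20 residues; the clade tree is then descended, applying independent
#' per-site substitutions with probability \code{subProb} on every branch
#' (clade-tree edges plus a final organism branch), so organisms in the same
#' clade receive more similar sequences than cross-clade pairs. Sequences
#' are attached only to (organism, reaction) cells with presence 1. Output
#' is byte-identical for identical (matrix, spec) inputs.
#'
#' @param m an [OrgMatrix-class] from [generateCladeMatrix()] (or any matrix
#'   over the spec's organisms).
#' @param spec the [CladeSpec-class] (supplies the clade tree, sequence
#'   length, substitution probability and seed).
#' @return \code{m} with sequences attached.
#' @examples
#' spec <- cladeSpec(list(c("a1", "a2"), c("b1", "b2")), subProb = 0)
#' m <- generateCladeSequences(generateCladeMatrix(spec), spec)
#' sequencesFor(m, "a1", "CORE001")
#' @export
generateCladeSequences <- function(m, spec) {
  stopifnot(is(m, "OrgMatrix"), is(spec, "CladeSpec"))
  orgs <- .cladeOrganisms(spec@clades)
  if (!all(orgs %in% organismIds(m)))
    stop("spec organisms missing from the matrix")
  set.seed(spec@seed)
  sequences <- list()
  for (rxn in reactionIds(m)) {
    root <- .AA20[sample.int(20L, spec@rootLength, replace = TRUE)]
    walk <- function(clades, parentSeq) {
      for (cl in clades) {
        nodeSeq <- .mutateSeq(parentSeq, spec@subProb)
        if (is.list(cl)) {
          walk(cl, nodeSeq)
        } else {
          for (org in cl) {
            orgSeq <- .mutateSeq(nodeSeq, spec@subProb)
            if (m@presence[org, rxn] == 1L)
              sequences[[.seqKey(org, rxn)]] <<-
                paste(orgSeq, collapse = "")
          }
        }
      }
    }
    walk(spec@clades, root)
  }
  orgMatrix(m@presence, catalog = m@catalog, sequences = sequences)
}

# resolve a multifurcation as a left ladder over min-label-sorted parts
.ladder <- function(parts) {
  parts <- parts[order(vapply(parts, `[[`, character(1), "min"))]
  acc <- parts[[1L]]
  for (k in seq_along(parts)[-1L])
    acc <- list(str = sprintf("(%s,%s)", acc$str, parts[[k]]$str),
                min = min(acc$min, parts[[k]]$min))
  acc
}

#' Planted tree of a CladeSpec
#'
#' The binary tree topology that deterministic UPGMA recovers from a
#' noise-free clade matrix: the nested clade structure, with every
#' grouping's members resolved as a ladder in leaf-label order (members of
#' one clade are mutually equidistant, and equal-distance merges are
#' resolved sequentially by smallest label).
#'
#' @param spec a [CladeSpec-class].
#' @return a canonical \code{phylo} tree (topology only, no branch lengths).
#' @examples
#' treeToNewick(plantedTree(cladeSpec(list(c("a1", "a2"), c("b1", "b2")))))
#' @export
plantedTree <- function(spec) {
  stopifnot(is(spec, "CladeSpec"))
  build <- function(clades) {
    parts <- lapply(clades, function(cl) {
      if (is.list(cl)) build(cl)
      else .ladder(lapply(sort(cl), function(o) list(str = o, min = o)))
    })
    .ladder(parts)
  }
  newickToTree(paste0(build(spec@clades)$str, ";"))
}
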