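#' @include AllClasses.R
NULL

#' Organism identifiers
#' @param x an object holding organisms.
#' @return character vector of organism ids.
#' @export
setGeneric("organismIds", function(x) standardGeneric("organismIds"))

#' Reaction identifiers
#' @param x an object holding a reaction catalog.
#' @return character vector of reaction ids.
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' Total number of catalog reactions (R_T)
#' @param x an object holding a reaction catalog.
#' @return integer.
#' @export
setGeneric("totalReactions", function(x) standardGeneric("totalReactions"))

#' Binary presence matrix
#' @param x an [OrgMatrix-class].
#' @return integer matrix (organisms x reactions).
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' Reaction catalog of an object
#' @param x an [OrgMatrix-class].
#' @return a [ReactionCatalog-class].
#' @export
setGeneric("catalog", function(x) standardGeneric("catalog"))

#' Similarity values
#' @param x a [SimilarityMatrix-class].
#' @return numeric symmetric matrix.
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' Penetration classes
#' @param x a [PenetrationProfile-class].
#' @return named character vector of class labels.
#' @export
setGeneric("penetrationClasses",
           function(x) standardGeneric("penetrationClasses"))

#' @rdname organismIds
#' @export
setMethod("organismIds", "OrgMatrix", function(x) rownames(x@presence))

#' @rdname organismIds
#' @export
setMethod("organismIds", "SimilarityMatrix", function(x) rownames(x@values))

#' @rdname reactionIds
#' @export
setMethod("reactionIds", "ReactionCatalog", function(x) x@reactionIds)

#' @rdname reactionIds
#' @export
setMethod("reactionIds", "OrgMatrix", function(x) x@catalog@reactionIds)

#' @rdname totalReactions
#' @export
setMethod("totalReactions", "ReactionCatalog",
          function(x) length(x@reactionIds))

#' @rdname totalReactions
#' @export
setMethod("totalReactions", "OrgMatrix",
          function(x) length(x@catalog@reactionIds))

#' @rdname presence
#' @export
setMethod("presence", "OrgMatrix", function(x) x@presence)

#' @rdname catalog
#' @export
setMethod("catalog", "OrgMatrix", function(x) x@catalog)

#' @rdname similarityValues
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

#' @rdname penetrationClasses
#' @export
setMethod("penetrationClasses", "PenetrationProfile", function(x) x@classes)

#' Sequences attached to one (organism, reaction) cell
#'
#' @param x an [OrgMatrix-class].
#' @param org organism id.
#' @param rxn reaction id.
#' @return character vector of amino-acid sequences, or NULL when no
#'   sequences are attached to the cell.
#' @export
sequencesFor <- function(x, org, rxn) {
  stopifnot(is(x, "OrgMatrix"))
  x@sequences[[.seqKey(org, rxn)]]
}

#' @describeIn OrgMatrix-class compact summary
#' @param object an OrgMatrix
#' @export
setMethod("show", "OrgMatrix", function(object) {
  p <- object@presence
  cat(sprintf("OrgMatrix: %d organisms x %d catalog reactions\n",
              nrow(p), ncol(p)))
  cat(sprintf("  present in >=1 organism: %d; all-absent (flagged): %d\n",
              sum(colSums(p) > 0), sum(colSums(p) == 0)))
  cat(sprintf("  sequence-annotated cells: %d\n", length(object@sequences)))
})

#' @describeIn ReactionCatalog-class compact summary
#' @param object a ReactionCatalog
#' @export
setMethod("show", "ReactionCatalog", function(object) {
  cat(sprintf("ReactionCatalog: %d reactions (%d with compounds, %d with pathways)\n",
              length(object@reactionIds), length(object@compounds),
              length(object@pathways)))
})

#' @describeIn SimilarityMatrix-class compact summary
#' @param object a SimilarityMatrix
#' @export
setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d organisms\n", object@method,
              nrow(object@values)))
  off <- object@values[upper.tri(object@values)]
  if (length(off))
    cat(sprintf("  off-diagonal range: [%.4g, %.4g]\n", min(off), max(off)))
})

#' @describeIn PenetrationProfile-class compact summary
#' @param object a PenetrationProfile
#' @export
setMethod("show", "PenetrationProfile", function(object) {
  tab <- table(factor(object@classes,
                      levels = c("LP", "MP", "HP", "UNCLASSIFIED")))
  cat(sprintf("PenetrationProfile over %d organisms, %d reactions\n",
              object@nOrganisms, length(object@counts)))
  cat(sprintf("  LP: %d  MP: %d  HP: %d  UNCLASSIFIED: %d\n",
              tab["LP"], tab["MP"], tab["HP"], tab["UNCLASSIFIED"]))
})

#' @describeIn TreeSimilarityResult-class compact summary
#' @param object a TreeSimilarityResult
#' @export
setMethod("show", "TreeSimilarityResult", function(object) {
  cat(sprintf("TreeSimilarityResult (%s): K = %.4f over %d leaves\n",
              object@mode, object@K, length(object@perLeaf)))
})

#' @describeIn StabilityReport-class compact summary
#' @param object a StabilityReport
#' @export
setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: L = %d replicates, %s mode, seed %d\n",
              object@replicates, object@countMode, object@seed))
  for (i in seq_along(object@zetas))
    cat(sprintf("  zeta = %-6g mean K = %.4f\n", object@zetas[i],
                object@meanK[i]))
})

#' Tree similarity score K
#' @param x a [TreeSimilarityResult-class].
#' @return numeric scalar in [0, 1].
#' @export
treeSimilarityK <- function(x) {
  stopifnot(is(x, "TreeSimilarityResult"))
  x@K
}

#' Per-leaf tree similarity scores F(xi)
#' @param x a [TreeSimilarityResult-class].
#' @return named numeric vector.
#' @export
perLeafScores <- function(x) {
  stopifnot(is(x, "TreeSimilarityResult"))
  x@perLeaf
}

#' Mean tree similarity per noise level
#' @param x a [StabilityReport-class].
#' @return named numeric vector K(zeta).
#' @export
meanK <- function(x) {
  stopifnot(is(x, "StabilityReport"))
  x@meanK
}

#' Per-organism correct-placement frequencies
#' @param x a [StabilityReport-class].
#' @return numeric matrix (organisms x zetas).
#' @export
placementProbabilities <- function(x) {
  stopifnot(is(x, "StabilityReport"))
  x@placement
}
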