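#' @include AllClasses.R
NULL

#' Jaccard index of two binary reaction vectors
#'
#' J(A, B) = |A intersect B| / |A union B| over the reactions present in at
#' least one of the two organisms.
#'
#' @param a,b binary vectors of equal length (0/1, logical accepted).
#' @param ids optional length-2 character vector naming the organisms, used
#'   in error messages.
#' @return numeric scalar in [0, 1].
#' @details Two all-zero vectors have an undefined index and raise an error
#'   naming the organisms: an organism with no reaction content carries no
#'   information for downstream clustering.
#' @examples
#' jaccardIndex(c(1, 1, 0, 1), c(1, 0, 0, 1))
#' @export
jaccardIndex <- function(a, b, ids = c("a", "b")) {
  if (length(a) != length(b))
    stop("presence vectors must have equal length")
  a <- as.logical(a); b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0L)
    stop(sprintf("Jaccard index undefined: organisms '%s' and '%s' share an empty reaction universe",
                 ids[1], ids[2]))
  sum(a & b) / union
}

#' All-to-all pairwise Jaccard similarity
#'
#' Binary metabolic fingerprint comparison: computes the Jaccard index for
#' every organism pair of the presence matrix. Columns are restricted to
#' reactions present in at least one loaded organism before comparison
#' (which leaves every pairwise index unchanged).
#'
#' @param m an [OrgMatrix-class] with at least two organisms.
#' @return A [SimilarityMatrix-class] with method tag "jaccard" and unit
#'   diagonal.
#' @examples
#' similarityValues(pairwiseJaccard(table5Fixture()$orgMatrix))
#' @export
pairwiseJaccard <- function(m) {
  stopifnot(is(m, "OrgMatrix"))
  p <- m@presence
  if (nrow(p) < 2L) stop("at least two organisms are required")
  p <- p[, colSums(p) > 0L, drop = FALSE]
  # |A ∩ B| via crossprod; |A ∪ B| = |A| + |B| - |A ∩ B|
  inter <- tcrossprod(p)
  sizes <- rowSums(p)
  union <- outer(sizes, sizes, "+") - inter
  if (any(union == 0))
    stop("organism pair with empty reaction universe")
  v <- inter / union
  diag(v) <- 1
  dimnames(v) <- list(rownames(p), rownames(p))
  new("SimilarityMatrix", values = v, method = "jaccard",
      parameters = list(nReactionsCompared = ncol(p)))
}
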