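#' @include AllClasses.R
NULL

# Resolve a substitution matrix name to the Biostrings score table.
.substitutionMatrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    stop(sprintf("substitution matrix '%s' is not available", name))
  get(name, envir = e)
}

# Raw Smith-Waterman local alignment score under the gap convention
# cost(k) = gapOpen + (k - 1) * gapExtend. Biostrings charges
# gapOpening + k * gapExtension per gap, hence the offset below.
.rawLocalScore <- function(seqA, seqB, cfg) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "local",
    substitutionMatrix = .substitutionMatrix(cfg@submatrix),
    gapOpening = cfg@gapOpen - cfg@gapExtend,
    gapExtension = cfg@gapExtend,
    scoreOnly = TRUE)
}

#' Normalized Smith-Waterman similarity of two enzyme sequences
#'
#' The raw local alignment score of \code{seqA} against \code{seqB},
#' normalized by the self-alignment score of the first sequence:
#' S(A_i, B_j) = sw(A_i, B_j) / sw(A_i, A_i). The score is directed: swapping
#' the arguments generally changes the value because the normalizing
#' self-score changes.
#'
#' @param seqA,seqB non-empty amino-acid sequences (character scalars).
#' @param cfg an [AlignmentConfig-class] (default: BLOSUM50 with linear gap
#'   cost 8).
#' @return numeric score; 1 for identical sequences, and at most 1 whenever
#'   no pair of distinct residues out-scores the diagonal.
#' @examples
#' normalizedSW("HEAGAWGHEE", "HEAGAWGHEE")
#' @seealso [reactionScore()], [organismSimilarity()]
#' @export
normalizedSW <- function(seqA, seqB, cfg = alignmentConfig()) {
  stopifnot(is(cfg, "AlignmentConfig"))
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("sequences must be non-empty")
  self <- .rawLocalScore(seqA, seqA, cfg)
  stopifnot(self > 0)  # positive diagonal of standard matrices guarantees this
  .rawLocalScore(seqA, seqB, cfg) / self
}

#' Aggregate an enzyme-pair score matrix to a reaction score
#'
#' The reaction-level similarity is the maximum over all (ordered) enzyme
#' pairs, independent of sequence lengths or how many isozymes/subunits each
#' organism carries.
#'
#' @param scores numeric matrix of pairwise enzyme scores (rows: organism A's
#'   enzymes, columns: organism B's).
#' @return the maximum score; attribute \code{which} holds the
#'   lexicographically first (row, column) attaining it.
#' @examples
#' aggregateEnzymeScores(table6Fixture())
#' @export
aggregateEnzymeScores <- function(scores) {
  scores <- as.matrix(scores)
  if (!length(scores) || !all(is.finite(scores)))
    stop("score matrix must be non-empty and finite")
  best <- max(scores)
  hit <- which(scores == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  structure(best, which = hit[1L, ])
}

#' Reaction-level similarity from two enzyme sequence sets
#'
#' Computes the directed normalized alignment score for every pair
#' (A_i, B_j) of enzymes catalyzing the same reaction in two organisms and
#' returns the maximum.
#'
#' @param seqsA,seqsB non-empty character vectors of amino-acid sequences.
#' @param cfg an [AlignmentConfig-class].
#' @return numeric reaction score (max over all pairs).
#' @examples
#' reactionScore("HEAGAWGHEE", c("HEAGAWGHEE", "PAWHEAE"))
#' @export
reactionScore <- function(seqsA, seqsB, cfg = alignmentConfig()) {
  if (!length(seqsA) || !length(seqsB))
    stop("both enzyme sequence sets must be non-empty")
  scores <- .enzymeScoreMatrix(seqsA, seqsB, cfg)
  as.numeric(aggregateEnzymeScores(scores))
}

# Directed normalized score matrix: rows A's enzymes (normalizers), cols B's.
# selfA may pass pre-computed self-scores for the rows.
.enzymeScoreMatrix <- function(seqsA, seqsB, cfg, selfA = NULL) {
  if (is.null(selfA))
    selfA <- vapply(seqsA, function(s) .rawLocalScore(s, s, cfg), numeric(1))
  raw <- matrix(0, length(seqsA), length(seqsB))
  for (i in seq_along(seqsA))
    for (j in seq_along(seqsB))
      raw[i, j] <- .rawLocalScore(seqsA[i], seqsB[j], cfg)
  raw / selfA
}
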