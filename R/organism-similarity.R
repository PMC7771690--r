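#' @include AllClasses.R alignment.R
NULL

# Normalize the penalty argument to list(mode, value).
.penaltyPolicy <- function(penalty) {
  if (identical(penalty, "ignore"))
    return(list(mode = "ignore", value = NA_real_))
  if (is.numeric(penalty) && length(penalty) == 1L && is.finite(penalty))
    return(list(mode = "value", value = as.numeric(penalty)))
  stop("penalty must be a finite numeric scalar or \"ignore\"")
}

#' Average organism similarity from a reaction score table
#'
#' Applies the penalty-aware average to a per-reaction score table: reactions
#' present in both organisms contribute their alignment score; reactions
#' present in exactly one organism (status ONE_SIDED) contribute the scalar
#' penalty (or are skipped entirely when \code{penalty = "ignore"});
#' reactions absent from both organisms (status ABSENT_BOTH) never
#' contribute. The similarity is the mean of the n_R contributing entries.
#'
#' @param table data.frame with columns \code{reaction}, \code{status} (one
#'   of \code{"SHARED"}, \code{"ONE_SIDED"}, \code{"ABSENT_BOTH"}) and
#'   \code{score} (numeric for SHARED rows), as produced by
#'   [organismSimilarity()] or [table5Fixture()].
#' @param penalty numeric scalar penalty for one-sided reactions, or the
#'   string \code{"ignore"}.
#' @return numeric similarity (mean of contributing entries); attribute
#'   \code{nR} records the number of contributing reactions.
#' @examples
#' tab <- table5Fixture()$scoreTable
#' averageSimilarity(tab, penalty = 0.25)
#' averageSimilarity(tab, penalty = "ignore")
#' @export
averageSimilarity <- function(table, penalty = 0.25) {
  pol <- .penaltyPolicy(penalty)
  stopifnot(all(c("reaction", "status", "score") %in% names(table)))
  if (!all(table$status %in% c("SHARED", "ONE_SIDED", "ABSENT_BOTH")))
    stop("invalid status in score table")
  vals <- table$score[table$status == "SHARED"]
  nOneSided <- sum(table$status == "ONE_SIDED")
  if (pol$mode == "value")
    vals <- c(vals, rep(pol$value, nOneSided))
  if (!length(vals))
    stop("no contributing reactions (n_R = 0); similarity undefined")
  structure(mean(vals), nR = length(vals))
}

# Per-pair directed score tables, sharing one raw alignment matrix per
# reaction. selfScores: environment cache keyed "org|rxn" -> numeric vector.
.pairScoreTables <- function(m, orgA, orgB, rxns, cfg, selfCache) {
  pA <- m@presence[orgA, rxns]
  pB <- m@presence[orgB, rxns]
  status <- ifelse(pA == 1L & pB == 1L, "SHARED",
                   ifelse(pA == 1L | pB == 1L, "ONE_SIDED", "ABSENT_BOTH"))
  scoreAB <- scoreBA <- rep(NA_real_, length(rxns))
  for (k in which(status == "SHARED")) {
    rxn <- rxns[k]
    seqsA <- sequencesFor(m, orgA, rxn)
    seqsB <- sequencesFor(m, orgB, rxn)
    if (is.null(seqsA) || is.null(seqsB))
      stop(sprintf("missing sequence(s) for present cell (%s, %s)",
                   if (is.null(seqsA)) orgA else orgB, rxn))
    selfA <- .cachedSelfScores(selfCache, m, orgA, rxn, cfg)
    selfB <- .cachedSelfScores(selfCache, m, orgB, rxn, cfg)
    raw <- matrix(0, length(seqsA), length(seqsB))
    for (i in seq_along(seqsA))
      for (j in seq_along(seqsB))
        raw[i, j] <- .rawLocalScore(seqsA[i], seqsB[j], cfg)
    scoreAB[k] <- max(raw / selfA)           # normalize rows by A's self-scores
    scoreBA[k] <- max(t(raw) / selfB)        # and columns by B's for B vs A
  }
  list(
    ab = data.frame(reaction = rxns, status = status, score = scoreAB,
                    stringsAsFactors = FALSE),
    ba = data.frame(reaction = rxns, status = status, score = scoreBA,
                    stringsAsFactors = FALSE))
}

.cachedSelfScores <- function(cache, m, org, rxn, cfg) {
  key <- .seqKey(org, rxn)
  if (is.null(cache[[key]]))
    cache[[key]] <- vapply(sequencesFor(m, org, rxn),
                           function(s) .rawLocalScore(s, s, cfg), numeric(1),
                           USE.NAMES = FALSE)
  cache[[key]]
}

#' Sequence-based similarity of one organism pair
#'
#' Directed enzyme-sequence similarity: for every reaction in scope, shared
#' reactions get the max-aggregated normalized alignment score of A's
#' enzymes against B's, one-sided reactions the penalty (or are skipped),
#' and reactions absent from both are excluded; the organism score is the
#' mean over the n_R contributing reactions. Both directed scores (A vs B
#' normalizes by A's self-scores; B vs A by B's) are returned with the full
#' per-reaction table.
#'
#' @param m an [OrgMatrix-class] carrying sequences.
#' @param orgA,orgB organism ids.
#' @param reactionSubset optional character vector restricting the reaction
#'   scope (must be a subset of the catalog); default: all catalog reactions.
#' @param penalty numeric scalar or \code{"ignore"} (default 0.25).
#' @param cfg an [AlignmentConfig-class].
#' @return list with \code{score} (directed A vs B), \code{scoreBA},
#'   \code{nR}, and \code{table} (per-reaction data.frame with both directed
#'   scores).
#' @seealso [pairwiseSequenceSimilarity()], [averageSimilarity()]
#' @export
organismSimilarity <- function(m, orgA, orgB, reactionSubset = NULL,
                               penalty = 0.25, cfg = alignmentConfig()) {
  stopifnot(is(m, "OrgMatrix"), is(cfg, "AlignmentConfig"))
  rxns <- .resolveSubset(m, reactionSubset)
  if (!all(c(orgA, orgB) %in% organismIds(m)))
    stop("unknown organism id")
  cache <- new.env(parent = emptyenv())
  tabs <- .pairScoreTables(m, orgA, orgB, rxns, cfg, cache)
  sAB <- tryCatch(averageSimilarity(tabs$ab, penalty), error = function(e)
    stop(sprintf("similarity undefined for pair (%s, %s) on the given subset: %s",
                 orgA, orgB, conditionMessage(e))))
  sBA <- averageSimilarity(tabs$ba, penalty)
  tab <- tabs$ab
  names(tab)[names(tab) == "score"] <- "scoreAB"
  tab$scoreBA <- tabs$ba$score
  list(score = as.numeric(sAB), scoreBA = as.numeric(sBA),
       nR = attr(sAB, "nR"), table = tab)
}

.resolveSubset <- function(m, reactionSubset) {
  if (is.null(reactionSubset))
    return(reactionIds(m))
  unknown <- setdiff(reactionSubset, reactionIds(m))
  if (length(unknown))
    stop("reaction subset not in catalog: ", paste(unknown, collapse = ", "))
  reactionSubset
}

#' All-to-all sequence-based organism similarity
#'
#' Fills the full organism similarity matrix from enzyme-sequence
#' comparisons over a reaction scope. Because the normalized alignment score
#' is directed, each pair is scored in both directions and the matrix entry
#' is their mean, making the result exactly symmetric; the direction
#' convention is recorded in the parameters. The diagonal is 1 (every
#' self-comparison aligns each enzyme to itself).
#'
#' @param m an [OrgMatrix-class] with sequences attached to every present
#'   cell within the subset scope.
#' @param reactionSubset optional character vector of reaction ids.
#' @param penalty numeric scalar or \code{"ignore"} (default 0.25).
#' @param cfg an [AlignmentConfig-class].
#' @return A [SimilarityMatrix-class] with method tag "sequence".
#' @export
pairwiseSequenceSimilarity <- function(m, reactionSubset = NULL,
                                       penalty = 0.25,
                                       cfg = alignmentConfig()) {
  stopifnot(is(m, "OrgMatrix"))
  orgs <- organismIds(m)
  if (length(orgs) < 2L) stop("at least two organisms are required")
  rxns <- .resolveSubset(m, reactionSubset)
  missing <- character()
  for (org in orgs)
    for (rxn in rxns[m@presence[org, rxns] == 1L])
      if (is.null(sequencesFor(m, org, rxn)))
        missing <- c(missing, .seqKey(org, rxn))
  if (length(missing))
    stop("present cells without sequences: ", paste(missing, collapse = ", "))

  cache <- new.env(parent = emptyenv())
  v <- matrix(1, length(orgs), length(orgs), dimnames = list(orgs, orgs))
  for (a in seq_len(length(orgs) - 1L)) {
    for (b in seq(a + 1L, length(orgs))) {
      tabs <- .pairScoreTables(m, orgs[a], orgs[b], rxns, cfg, cache)
      sAB <- averageSimilarity(tabs$ab, penalty)
      sBA <- averageSimilarity(tabs$ba, penalty)
      v[a, b] <- v[b, a] <- (as.numeric(sAB) + as.numeric(sBA)) / 2
    }
  }
  pol <- .penaltyPolicy(penalty)
  new("SimilarityMatrix", values = v, method = "sequence",
      parameters = list(
        penaltyMode = pol$mode, penaltyValue = pol$value,
        submatrix = cfg@submatrix, gapOpen = cfg@gapOpen,
        gapExtend = cfg@gapExtend,
        reactionSubset = if (is.null(reactionSubset)) "all" else reactionSubset,
        symmetrization = "mean of the two directed organism scores"))
}

#' Export a per-reaction score table as long-format TSV
#'
#' @param table per-reaction data.frame from [organismSimilarity()].
#' @param orgA,orgB the organism ids of the pair.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeScoreTable <- function(table, orgA, orgB, path) {
  out <- data.frame(org_a = orgA, org_b = orgB, table,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
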