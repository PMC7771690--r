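#' @include AllClasses.R
NULL

#' Read an organism-reaction matrix, optionally with enzyme sequences
#'
#' Reads the tab-separated presence matrix dialect: a header row whose first
#' cell is \code{organism} followed by reaction ids, then one row per
#' organism with entries 0 or 1. Optionally attaches amino-acid sequences
#' from a FASTA file whose headers follow
#' \code{orgID|reactionID[|geneID]}; multiple records may target the same
#' (organism, reaction) cell (isozymes, complex subunits).
#'
#' @param matrixPath path to the TSV presence matrix.
#' @param fastaPath optional path to a FASTA file of enzyme sequences.
#' @return A validated [OrgMatrix-class]. Reactions absent from every
#'   organism are retained in the catalog (they remain available to the
#'   random penetration null model) but carry all-zero columns.
#' @details A FASTA record addressing a cell whose presence entry is 0 is a
#'   consistency error naming the record; non-binary matrix entries and
#'   duplicated organism or reaction ids are format errors.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeOrgMatrix(table5Fixture()$orgMatrix, f)
#' m <- readOrgMatrix(f)
#' presence(m)["A", "R01"]
#' @seealso [writeOrgMatrix()], [readReactionAnnotations()]
#' @export
readOrgMatrix <- function(matrixPath, fastaPath = NULL) {
  raw <- utils::read.delim(matrixPath, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("matrix file must contain an organism column and >=1 reaction column")
  orgs <- as.character(raw[[1L]])
  if (anyDuplicated(orgs))
    stop("duplicate organism id(s): ",
         paste(unique(orgs[duplicated(orgs)]), collapse = ", "))
  rxns <- colnames(raw)[-1L]
  if (anyDuplicated(rxns))
    stop("duplicate reaction id(s): ",
         paste(unique(rxns[duplicated(rxns)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  ok <- matrix(vals %in% c(0, 1), nrow = nrow(vals))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-binary entry '%s' at organism '%s', reaction '%s'",
                 vals[bad[1, 1], bad[1, 2]], orgs[bad[1, 1]],
                 rxns[bad[1, 2]]))
  }
  storage.mode(vals) <- "integer"
  dimnames(vals) <- list(orgs, rxns)

  sequences <- list()
  if (!is.null(fastaPath)) {
    fa <- Biostrings::readAAStringSet(fastaPath)
    if (length(fa)) {
      heads <- sub("\\s.*$", "", names(fa))
      parts <- strsplit(heads, "|", fixed = TRUE)
      for (k in seq_along(fa)) {
        pt <- parts[[k]]
        if (length(pt) < 2L)
          stop("FASTA header not in 'org|reaction[|gene]' form: ", heads[k])
        org <- pt[1]; rxn <- pt[2]
        if (!(org %in% orgs) || !(rxn %in% rxns))
          stop("FASTA record references unknown organism/reaction: ", heads[k])
        if (vals[org, rxn] != 1L)
          stop(sprintf(
            "FASTA record '%s' targets cell (%s, %s) with presence 0",
            heads[k], org, rxn))
        key <- .seqKey(org, rxn)
        sequences[[key]] <- c(sequences[[key]], as.character(fa[[k]]))
      }
    }
  }
  orgMatrix(vals, sequences = sequences)
}

#' Write an organism-reaction matrix (and optionally its sequences)
#'
#' Emits the TSV dialect read by [readOrgMatrix()]; when the matrix carries
#' sequences and \code{fastaPath} is given, they are written as FASTA with
#' \code{org|reaction|g<k>} headers so a read/write/read round trip is exact.
#'
#' @param m an [OrgMatrix-class].
#' @param matrixPath output TSV path.
#' @param fastaPath optional output FASTA path for attached sequences.
#' @return Invisibly, \code{matrixPath}.
#' @export
writeOrgMatrix <- function(m, matrixPath, fastaPath = NULL) {
  stopifnot(is(m, "OrgMatrix"))
  df <- data.frame(organism = organismIds(m), m@presence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fastaPath)) {
    con <- file(fastaPath, "w")
    on.exit(close(con))
    for (key in names(m@sequences)) {
      seqs <- m@sequences[[key]]
      for (k in seq_along(seqs))
        writeLines(c(sprintf(">%s|g%d", key, k), seqs[k]), con)
    }
  }
  invisible(matrixPath)
}

#' Read reaction-to-compound / reaction-to-pathway annotation tables
#'
#' Long-format TSV with two columns, \code{reaction<TAB>compound} or
#' \code{reaction<TAB>pathway}. A row with an empty second field records a
#' reaction explicitly annotated with an empty set (e.g. "no pathway
#' assigned"), which is distinct from the reaction being absent from the
#' table.
#'
#' @param path TSV path.
#' @return named list: reaction id -> character vector of annotation ids
#'   (possibly empty).
#' @seealso [lpHpOverlap()]
#' @export
readReactionAnnotations <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = NULL)
  if (ncol(raw) != 2L)
    stop("annotation table must have exactly two columns")
  rxn <- as.character(raw[[1L]])
  ann <- as.character(raw[[2L]])
  out <- lapply(split(ann, rxn), function(v) v[nzchar(v)])
  out[unique(rxn)]
}

#' Read a reaction subset list
#'
#' Plain text, one reaction id per line; \code{#} starts a comment and blank
#' lines are ignored.
#'
#' @param path file path.
#' @return character vector of reaction ids.
#' @seealso [organismSimilarity()], [pairwiseSequenceSimilarity()]
#' @export
readReactionSubset <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
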