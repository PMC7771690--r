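#' @import methods
#' @importFrom stats setNames
NULL

# Amino-acid alphabet accepted in sequence slots: 20 standard residues plus X.
.AA_ALPHABET_RE <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

#' ReactionCatalog: the reaction universe of a study
#'
#' Holds the ordered set of reaction identifiers covered by an organism set,
#' together with optional reaction-to-compound and reaction-to-pathway
#' annotation maps. The total number of reactions in the catalog (including
#' reactions currently absent from every loaded organism) is the universe from
#' which the random penetration null model draws.
#'
#' @slot reactionIds character vector of unique reaction identifiers.
#' @slot compounds named list: reaction id -> character vector of compound ids.
#' @slot pathways named list: reaction id -> character vector of pathway ids
#'   (may be an empty vector, meaning "no pathway assigned").
#'
#' @seealso [reactionCatalog()], [totalReactions()]
#' @exportClass ReactionCatalog
setClass("ReactionCatalog",
  representation(
    reactionIds = "character",
    compounds = "list",
    pathways = "list"
  ),
  prototype(compounds = list(), pathways = list())
)

setValidity("ReactionCatalog", function(object) {
  msg <- character()
  if (length(object@reactionIds) < 1L)
    msg <- c(msg, "catalog must contain at least one reaction")
  if (anyDuplicated(object@reactionIds))
    msg <- c(msg, "reaction ids must be unique")
  for (nm in c("compounds", "pathways")) {
    keys <- names(slot(object, nm))
    if (length(slot(object, nm)) && (is.null(keys) ||
        !all(keys %in% object@reactionIds)))
      msg <- c(msg, sprintf("all %s keys must be catalog reaction ids", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReactionCatalog
#'
#' @param reactionIds character vector of unique reaction identifiers.
#' @param compounds optional named list mapping reaction ids to character
#'   vectors of compound ids.
#' @param pathways optional named list mapping reaction ids to character
#'   vectors of pathway ids; an empty vector means the reaction has no
#'   pathway assignment.
#' @return A [ReactionCatalog-class] object.
#' @examples
#' reactionCatalog(c("R01", "R02"), compounds = list(R01 = c("C1", "C2")))
#' @export
reactionCatalog <- function(reactionIds, compounds = list(), pathways = list()) {
  new("ReactionCatalog", reactionIds = as.character(reactionIds),
      compounds = compounds, pathways = pathways)
}

#' OrgMatrix: organism-reaction presence matrix with optional enzyme sequences
#'
#' The central data container: a binary N x R_T presence matrix (rows =
#' organisms, columns = catalog reactions) optionally annotated with the
#' amino-acid sequences of the enzymes catalyzing each present reaction in
#' each organism. Sequences are attached per (organism, reaction) cell and are
#' only permitted where the presence entry is 1.
#'
#' @slot presence integer matrix in {0,1}; rownames are organism ids, colnames
#'   the catalog reaction ids.
#' @slot catalog a [ReactionCatalog-class].
#' @slot sequences named list keyed \code{"<org>|<rxn>"}; each element a
#'   non-empty character vector of amino-acid sequences (20-letter alphabet
#'   plus X).
#'
#' @seealso [orgMatrix()], [readOrgMatrix()], [pairwiseJaccard()],
#'   [penetrationProfile()]
#' @exportClass OrgMatrix
setClass("OrgMatrix",
  representation(
    presence = "matrix",
    catalog = "ReactionCatalog",
    sequences = "list"
  ),
  prototype(sequences = list())
)

.seqKey <- function(org, rxn) paste(org, rxn, sep = "|")

setValidity("OrgMatrix", function(object) {
  msg <- character()
  p <- object@presence
  if (is.null(rownames(p)) || is.null(colnames(p)))
    return("presence matrix must have organism rownames and reaction colnames")
  if (anyDuplicated(rownames(p)))
    msg <- c(msg, "organism ids must be unique")
  if (!identical(colnames(p), object@catalog@reactionIds))
    msg <- c(msg, "presence columns must match the catalog reaction ids")
  if (!all(p %in% c(0L, 1L)))
    msg <- c(msg, "presence entries must be 0 or 1")
  if (any(rowSums(p) < 1))
    msg <- c(msg, sprintf("organisms with no present reaction: %s",
                          paste(rownames(p)[rowSums(p) < 1], collapse = ", ")))
  if (length(object@sequences)) {
    keys <- names(object@sequences)
    parts <- strsplit(keys, "|", fixed = TRUE)
    bad <- vapply(seq_along(keys), function(k) {
      pt <- parts[[k]]
      length(pt) != 2L || !(pt[1] %in% rownames(p)) ||
        !(pt[2] %in% colnames(p)) || p[pt[1], pt[2]] != 1L
    }, logical(1))
    if (any(bad))
      msg <- c(msg, sprintf(
        "sequences attached to cells without presence: %s",
        paste(keys[bad], collapse = ", ")))
    empty <- lengths(object@sequences) == 0L
    if (any(empty))
      msg <- c(msg, "sequence entries must be non-empty")
    alpha_ok <- vapply(object@sequences, function(s)
      all(grepl(.AA_ALPHABET_RE, s)), logical(1))
    if (!all(alpha_ok))
      msg <- c(msg, sprintf(
        "non amino-acid characters in sequences for: %s",
        paste(names(object@sequences)[!alpha_ok], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OrgMatrix
#'
#' @param presence binary matrix (rows = organisms, columns = reactions) with
#'   dimnames set.
#' @param catalog optional [ReactionCatalog-class]; defaults to a catalog made
#'   of the presence colnames.
#' @param sequences optional named list keyed \code{"<org>|<rxn>"} of character
#'   vectors of amino-acid sequences.
#' @return An [OrgMatrix-class] object.
#' @examples
#' p <- rbind(A = c(R01 = 1, R02 = 1), B = c(R01 = 1, R02 = 0))
#' orgMatrix(p)
#' @export
orgMatrix <- function(presence, catalog = NULL, sequences = list()) {
  storage.mode(presence) <- "integer"
  if (is.null(catalog))
    catalog <- reactionCatalog(colnames(presence))
  new("OrgMatrix", presence = presence, catalog = catalog,
      sequences = sequences)
}

#' PenetrationProfile: per-reaction penetration counts and classes
#'
#' For every reaction present in at least one organism, the number of
#' organisms containing it, the corresponding fraction of N, and the
#' penetration class: LP (low penetration), MP (medium), HP (high) or
#' UNCLASSIFIED for fractions falling between the class bands.
#'
#' @slot counts named integer vector (reaction -> organism count), restricted
#'   to reactions present in at least one organism.
#' @slot fractions counts / N.
#' @slot classes named character vector with values in
#'   \code{c("LP", "MP", "HP", "UNCLASSIFIED")}.
#' @slot thresholds numeric vector \code{c(lpMax, mpLo, mpHi, hpMin)}.
#' @slot nOrganisms integer N.
#'
#' @seealso [penetrationProfile()]
#' @exportClass PenetrationProfile
setClass("PenetrationProfile",
  representation(
    counts = "integer",
    fractions = "numeric",
    classes = "character",
    thresholds = "numeric",
    nOrganisms = "integer"
  )
)

setValidity("PenetrationProfile", function(object) {
  msg <- character()
  n <- object@nOrganisms
  if (any(object@counts < 1L) || any(object@counts > n))
    msg <- c(msg, "counts must lie in 1..N")
  if (!all(object@classes %in% c("LP", "MP", "HP", "UNCLASSIFIED")))
    msg <- c(msg, "invalid penetration class label")
  if (!identical(names(object@counts), names(object@classes)))
    msg <- c(msg, "counts and classes must be named consistently")
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: pairwise organism similarity scores
#'
#' Symmetric N x N organism similarity matrix tagged with the comparison
#' method ("jaccard" or "sequence") and its parameters (penalty policy,
#' alignment configuration, reaction subset).
#'
#' @slot values numeric symmetric matrix with organism dimnames.
#' @slot method character, "jaccard" or "sequence".
#' @slot parameters list of method-specific settings.
#'
#' @seealso [pairwiseJaccard()], [pairwiseSequenceSimilarity()],
#'   [similarityToDistance()]
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(
    values = "matrix",
    method = "character",
    parameters = "list"
  ),
  prototype(parameters = list())
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must be square with matching organism dimnames")
  if (!all(is.finite(v)))
    msg <- c(msg, "similarity values must be finite")
  if (!isSymmetric(unname(v), tol = 1e-12))
    msg <- c(msg, "similarity matrix must be symmetric")
  if (!object@method %in% c("jaccard", "sequence"))
    msg <- c(msg, "method must be 'jaccard' or 'sequence'")
  if (object@method == "jaccard" && any(abs(diag(v) - 1) > 1e-12))
    msg <- c(msg, "jaccard similarity must have unit diagonal")
  if (length(msg)) msg else TRUE
})

#' AlignmentConfig: local alignment scoring parameters
#'
#' Scoring configuration for Smith-Waterman local alignment of enzyme
#' sequences. A gap of length k costs \code{gapOpen + (k - 1) * gapExtend};
#' the default (8, 8) is a linear gap cost of 8 per residue.
#'
#' @slot submatrix name of an amino-acid substitution matrix available in
#'   Biostrings (default "BLOSUM50").
#' @slot gapOpen positive cost of the first residue of a gap.
#' @slot gapExtend positive cost of each further gap residue.
#'
#' @seealso [alignmentConfig()], [normalizedSW()]
#' @exportClass AlignmentConfig
setClass("AlignmentConfig",
  representation(
    submatrix = "character",
    gapOpen = "numeric",
    gapExtend = "numeric"
  )
)

setValidity("AlignmentConfig", function(object) {
  msg <- character()
  if (object@gapOpen <= 0 || object@gapExtend <= 0)
    msg <- c(msg, "gap costs must be positive")
  ok <- tryCatch({
    .substitutionMatrix(object@submatrix); TRUE
  }, error = function(e) FALSE)
  if (!ok)
    msg <- c(msg, sprintf("unknown substitution matrix '%s'", object@submatrix))
  if (length(msg)) msg else TRUE
})

#' Construct an AlignmentConfig
#'
#' @param submatrix substitution matrix name (default "BLOSUM50").
#' @param gapOpen cost of the first gap residue (default 8).
#' @param gapExtend cost of each additional gap residue (default 8; equal to
#'   \code{gapOpen} this is a linear gap cost).
#' @return An [AlignmentConfig-class] object.
#' @examples
#' alignmentConfig()
#' @export
alignmentConfig <- function(submatrix = "BLOSUM50", gapOpen = 8, gapExtend = 8) {
  new("AlignmentConfig", submatrix = submatrix, gapOpen = gapOpen,
      gapExtend = gapExtend)
}

#' TreeSimilarityResult: leaf-neighborhood tree similarity
#'
#' Result of comparing two trees over the same leaf set: the per-leaf scores
#' F(xi) and their mean K. In binary mode F(xi) is 1 exactly when the leaf's
#' parent clade is identical in both trees; in weighted mode F(xi) is a
#' distance-weighted average of clade matches in [0, 1].
#'
#' @slot K numeric scalar in [0, 1], the mean of the per-leaf scores.
#' @slot perLeaf named numeric vector of per-leaf scores.
#' @slot mode "binary" or "weighted".
#'
#' @seealso [binaryTreeSimilarity()], [weightedTreeSimilarity()]
#' @exportClass TreeSimilarityResult
setClass("TreeSimilarityResult",
  representation(K = "numeric", perLeaf = "numeric", mode = "character")
)

setValidity("TreeSimilarityResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("binary", "weighted"))
    msg <- c(msg, "mode must be 'binary' or 'weighted'")
  if (abs(object@K - mean(object@perLeaf)) > 1e-9)
    msg <- c(msg, "K must equal the mean of the per-leaf scores")
  if (any(object@perLeaf < -1e-12 | object@perLeaf > 1 + 1e-12))
    msg <- c(msg, "per-leaf scores must lie in [0, 1]")
  if (object@mode == "binary" && !all(object@perLeaf %in% c(0, 1)))
    msg <- c(msg, "binary-mode per-leaf scores must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' StabilityReport: tree robustness under reaction-content noise
#'
#' Summary of the noise-injection sensitivity analysis: mean tree similarity
#' K(zeta) to the unperturbed reference tree, and the per-organism frequency
#' of correct placement (replicates in which the organism's parent clade is
#' unchanged), for each noise level zeta.
#'
#' @slot zetas numeric vector of noise levels.
#' @slot meanK named numeric vector, mean K per zeta.
#' @slot placement numeric matrix (organisms x zetas) of correct-placement
#'   frequencies in [0, 1].
#' @slot replicates integer L, perturbation replicates per zeta.
#' @slot seed integer seed used.
#' @slot countMode "deterministic_round" or "bernoulli".
#'
#' @seealso [stabilityAnalysis()]
#' @exportClass StabilityReport
setClass("StabilityReport",
  representation(
    zetas = "numeric",
    meanK = "numeric",
    placement = "matrix",
    replicates = "integer",
    seed = "integer",
    countMode = "character"
  )
)

setValidity("StabilityReport", function(object) {
  msg <- character()
  if (any(object@placement < 0 | object@placement > 1))
    msg <- c(msg, "placement frequencies must lie in [0, 1]")
  if (any(object@meanK < -1e-12 | object@meanK > 1 + 1e-12))
    msg <- c(msg, "mean K must lie in [0, 1]")
  if (object@replicates < 1L)
    msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CladeSpec: recipe for clade-structured synthetic data
#'
#' Describes a planted organism grouping and reaction strata for the synthetic
#' data generators: core reactions shared by every organism (high
#' penetration), clade reactions shared within one clade (medium penetration
#' at balanced clade sizes), and private reactions unique to single organisms
#' (low penetration). The clade tree also drives the synthetic sequence
#' divergence model: one root sequence per reaction, independently mutated
#' per site along each branch of the clade tree.
#'
#' @slot clades nested list; each element is either a character vector of
#'   organism ids (a terminal clade) or a further list of sub-clades.
#' @slot coreReactions integer, number of reactions present in all organisms.
#' @slot cladeReactions integer, number of reactions private to each terminal
#'   clade.
#' @slot privateReactions integer, number of reactions private to each
#'   organism.
#' @slot rootLength integer, root sequence length in residues.
#' @slot subProb per-site substitution probability applied on each branch of
#'   the clade tree, in [0, 1).
#' @slot seed integer seed making generation deterministic.
#'
#' @seealso [cladeSpec()], [generateCladeMatrix()], [generateCladeSequences()]
#' @exportClass CladeSpec
setClass("CladeSpec",
  representation(
    clades = "list",
    coreReactions = "integer",
    cladeReactions = "integer",
    privateReactions = "integer",
    rootLength = "integer",
    subProb = "numeric",
    seed = "integer"
  )
)

.cladeOrganisms <- function(clades) {
  unlist(lapply(clades, function(cl)
    if (is.list(cl)) .cladeOrganisms(cl) else cl), use.names = FALSE)
}

setValidity("CladeSpec", function(object) {
  msg <- character()
  orgs <- .cladeOrganisms(object@clades)
  if (length(orgs) < 2L)
    msg <- c(msg, "at least two organisms are required")
  if (anyDuplicated(orgs))
    msg <- c(msg, sprintf("duplicated organism ids: %s",
                          paste(unique(orgs[duplicated(orgs)]), collapse = ", ")))
  if (object@coreReactions < 0L || object@cladeReactions < 0L ||
      object@privateReactions < 0L)
    msg <- c(msg, "reaction counts must be non-negative")
  if (object@coreReactions + object@cladeReactions +
      object@privateReactions < 1L)
    msg <- c(msg, "at least one reaction stratum must be non-empty")
  if (object@subProb < 0 || object@subProb >= 1)
    msg <- c(msg, "subProb must lie in [0, 1)")
  if (object@rootLength < 1L)
    msg <- c(msg, "rootLength must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CladeSpec
#'
#' @param clades nested list of organism groupings; each element is a
#'   character vector of organism ids or a further list of sub-clades.
#' @param coreReactions reactions shared by every organism (default 40).
#' @param cladeReactions reactions private to each terminal clade (default 15).
#' @param privateReactions reactions private to each organism (default 5).
#' @param rootLength root sequence length (default 120 residues).
#' @param subProb per-site, per-branch substitution probability (default 0.05).
#' @param seed integer seed (default 1).
#' @return A [CladeSpec-class] object.
#' @examples
#' cladeSpec(list(paste0("a", 1:5), paste0("b", 1:5)))
#' @export
cladeSpec <- function(clades, coreReactions = 40L, cladeReactions = 15L,
                      privateReactions = 5L, rootLength = 120L,
                      subProb = 0.05, seed = 1L) {
  new("CladeSpec", clades = clades,
      coreReactions = as.integer(coreReactions),
      cladeReactions = as.integer(cladeReactions),
      privateReactions = as.integer(privateReactions),
      rootLength = as.integer(rootLength),
      subProb = subProb, seed = as.integer(seed))
}
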