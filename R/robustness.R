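#' @include jaccard.R treebuild.R treecompare.R
NULL

#' Perturb reaction content at noise level zeta
#'
#' Randomly swaps part of each organism's reaction set for reactions it does
#' not carry, keeping every organism's reaction count constant. In
#' \code{"deterministic_round"} mode exactly \code{round(zeta * R_E)}
#' present reactions are removed (uniformly, without replacement) and the
#' same number of absent reactions added; in \code{"bernoulli"} mode each
#' present reaction is independently swapped with probability zeta.
#' Replacements are drawn uniformly without replacement from the catalog
#' reactions absent from the organism, so a removed reaction is never
#' re-added within the same perturbation.
#'
#' Uses the current RNG state; seed upstream (e.g. [stabilityAnalysis()]
#' seeds once per analysis).
#'
#' @param m an [OrgMatrix-class].
#' @param zeta noise level in [0, 1).
#' @param countMode \code{"deterministic_round"} (default) or
#'   \code{"bernoulli"}.
#' @return a perturbed [OrgMatrix-class] with identical row sums. Attached
#'   sequences are dropped (they would no longer match the presence
#'   pattern); the perturbed matrix is meant for binary fingerprint
#'   analysis.
#' @examples
#' set.seed(1)
#' m <- generateCladeMatrix(cladeSpec(list(paste0("a", 1:5), paste0("b", 1:5))))
#' rowSums(presence(perturbMatrix(m, 0.1))) == rowSums(presence(m))
#' @export
perturbMatrix <- function(m, zeta,
                          countMode = c("deterministic_round", "bernoulli")) {
  stopifnot(is(m, "OrgMatrix"))
  countMode <- match.arg(countMode)
  if (zeta < 0 || zeta >= 1) stop("zeta must lie in [0, 1)")
  p <- m@presence
  if (zeta == 0) return(orgMatrix(p, catalog = m@catalog))
  for (org in rownames(p)) {
    pres <- which(p[org, ] == 1L)
    abs_ <- which(p[org, ] == 0L)
    nswap <- if (countMode == "deterministic_round") {
      round(zeta * length(pres))
    } else {
      sum(stats::runif(length(pres)) < zeta)
    }
    if (nswap == 0L) next
    if (nswap > length(abs_))
      stop(sprintf(
        "organism '%s': %d swaps requested but only %d absent reactions",
        org, nswap, length(abs_)))
    drop <- pres[sample.int(length(pres), nswap)]
    add <- abs_[sample.int(length(abs_), nswap)]
    p[org, drop] <- 0L
    p[org, add] <- 1L
  }
  orgMatrix(p, catalog = m@catalog)
}

#' Noise-injection sensitivity analysis of the fingerprint tree
#'
#' Measures the robustness of the binary-fingerprint UPGMA tree to random
#' reaction-content noise. The unperturbed (zeta = 0) tree is built once as
#' the reference; then, for each noise level and replicate, the whole matrix
#' is perturbed with [perturbMatrix()], the Jaccard/UPGMA tree rebuilt, and
#' compared to the reference with [binaryTreeSimilarity()]. Reported are
#' the mean tree similarity K(zeta) over the L replicates and, per organism,
#' the fraction of replicates in which its parent clade was unchanged
#' (correct placement).
#'
#' @param m an [OrgMatrix-class] with N >= 3 organisms.
#' @param zetas numeric vector of noise levels in [0, 1).
#' @param L replicates per noise level (>= 1).
#' @param seed integer seed; the full report is reproducible given
#'   (seed, L, zetas, matrix).
#' @param countMode passed to [perturbMatrix()].
#' @return a [StabilityReport-class].
#' @examples
#' m <- generateCladeMatrix(cladeSpec(list(paste0("a", 1:4), paste0("b", 1:4))))
#' stabilityAnalysis(m, zetas = c(0, 0.1), L = 20, seed = 1)
#' @export
stabilityAnalysis <- function(m, zetas, L, seed = 1L,
                              countMode = c("deterministic_round",
                                            "bernoulli")) {
  stopifnot(is(m, "OrgMatrix"))
  countMode <- match.arg(countMode)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (nrow(m@presence) < 3L) stop("at least three organisms are required")

  ref <- upgmaTree(similarityToDistance(pairwiseJaccard(m)))
  orgs <- sort(organismIds(m))
  set.seed(as.integer(seed))
  meanK <- setNames(numeric(length(zetas)), as.character(zetas))
  placement <- matrix(0, length(orgs), length(zetas),
                      dimnames = list(orgs, as.character(zetas)))
  for (z in seq_along(zetas)) {
    ksum <- 0
    correct <- setNames(numeric(length(orgs)), orgs)
    for (rep in seq_len(L)) {
      pert <- perturbMatrix(m, zetas[z], countMode)
      tree <- tryCatch(
        upgmaTree(similarityToDistance(pairwiseJaccard(pert))),
        error = function(e) stop(sprintf("replicate %d (zeta = %g): %s",
                                         rep, zetas[z],
                                         conditionMessage(e))))
      res <- binaryTreeSimilarity(ref, tree)
      ksum <- ksum + res@K
      correct <- correct + (res@perLeaf[orgs] == 1)
    }
    meanK[z] <- ksum / L
    placement[, z] <- correct / L
  }
  new("StabilityReport", zetas = as.numeric(zetas), meanK = meanK,
      placement = placement, replicates = L, seed = as.integer(seed),
      countMode = countMode)
}

#' Write a StabilityReport as TSV + JSON summary
#'
#' @param report a [StabilityReport-class].
#' @param tsvPath per-organism placement table output path.
#' @param jsonPath optional JSON summary (mean K per zeta, parameters).
#' @return invisibly, \code{tsvPath}.
#' @export
writeStabilityReport <- function(report, tsvPath, jsonPath = NULL) {
  stopifnot(is(report, "StabilityReport"))
  df <- data.frame(organism = rownames(report@placement),
                   report@placement, check.names = FALSE)
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(zetas = report@zetas, meanK = unname(report@meanK),
           replicates = report@replicates, seed = report@seed,
           countMode = report@countMode),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsvPath)
}
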