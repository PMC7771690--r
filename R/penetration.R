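#' @include AllClasses.R
NULL

#' Reaction penetration profile
#'
#' Classifies every reaction present in at least one organism by its
#' penetration, the fraction of the N organisms containing it: low
#' penetration (LP) strictly below \code{lpMax}, medium penetration (MP)
#' inside the closed band [\code{mpLo}, \code{mpHi}], high penetration (HP)
#' strictly above \code{hpMin}. Fractions between the bands are labelled
#' UNCLASSIFIED. Reactions absent from every loaded organism are excluded
#' from the profile (they stay in the catalog).
#'
#' @param m an [OrgMatrix-class].
#' @param lpMax LP upper bound (default 0.10, exclusive).
#' @param mpLo MP lower bound (default 0.35, inclusive).
#' @param mpHi MP upper bound (default 0.65, inclusive).
#' @param hpMin HP lower bound (default 0.90, exclusive).
#' @return A [PenetrationProfile-class].
#' @examples
#' m <- generateCladeMatrix(cladeSpec(list(paste0("a", 1:5), paste0("b", 1:5))))
#' penetrationProfile(m)
#' @export
penetrationProfile <- function(m, lpMax = 0.10, mpLo = 0.35, mpHi = 0.65,
                               hpMin = 0.90) {
  stopifnot(is(m, "OrgMatrix"))
  if (!(lpMax > 0 && lpMax <= mpLo && mpLo <= mpHi && mpHi <= hpMin &&
        hpMin < 1))
    stop("thresholds must satisfy 0 < lpMax <= mpLo <= mpHi <= hpMin < 1")
  counts <- colSums(m@presence)
  counts <- counts[counts > 0L]
  n <- nrow(m@presence)
  frac <- counts / n
  classes <- rep("UNCLASSIFIED", length(frac))
  classes[frac < lpMax] <- "LP"
  classes[frac >= mpLo & frac <= mpHi] <- "MP"
  classes[frac > hpMin] <- "HP"
  names(classes) <- names(counts)
  new("PenetrationProfile",
      counts = setNames(as.integer(counts), names(counts)),
      fractions = frac, classes = classes,
      thresholds = c(lpMax = lpMax, mpLo = mpLo, mpHi = mpHi, hpMin = hpMin),
      nOrganisms = nrow(m@presence))
}

#' Per-organism penetration-class composition
#'
#' For each organism, the fraction of its present reactions falling into
#' each penetration class. LP + MP + HP + UNCLASSIFIED sums to 1 per
#' organism.
#'
#' @param m the [OrgMatrix-class] the profile was computed from.
#' @param p a [PenetrationProfile-class] from [penetrationProfile()] on
#'   \code{m}.
#' @return data.frame with columns \code{organism}, \code{nReactions},
#'   \code{LP}, \code{MP}, \code{HP}, \code{UNCLASSIFIED} (fractions).
#' @export
organismComposition <- function(m, p) {
  stopifnot(is(m, "OrgMatrix"), is(p, "PenetrationProfile"))
  if (p@nOrganisms != nrow(m@presence) ||
      !all(names(p@counts) %in% reactionIds(m)))
    stop("profile was not computed from this matrix")
  cls <- p@classes
  levels <- c("LP", "MP", "HP", "UNCLASSIFIED")
  out <- lapply(organismIds(m), function(org) {
    rxns <- colnames(m@presence)[m@presence[org, ] == 1L]
    tab <- table(factor(cls[rxns], levels = levels))
    c(nReactions = length(rxns), tab / length(rxns))
  })
  df <- as.data.frame(do.call(rbind, out))
  data.frame(organism = organismIds(m), df, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Random penetration null model
#'
#' Monte-Carlo null for the shared-reaction histogram: in each replicate,
#' every organism i draws its true reaction count R_i reactions uniformly
#' without replacement from the full catalog (R_T reactions, including any
#' absent from all loaded organisms). Returns the mean and standard
#' deviation, over replicates, of (a) the histogram of shared-reaction
#' counts (how many reactions are present in exactly k organisms,
#' k = 0..N) and (b) the per-reaction organism count, whose analytic
#' expectation is sum_i R_i / R_T for every reaction.
#'
#' @param m an [OrgMatrix-class].
#' @param replicates number of random draws (>= 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @return list with \code{histMean}, \code{histSD} (named numeric vectors
#'   over counts 0..N), \code{perReactionMean}, \code{perReactionSD} (named
#'   by reaction), \code{expectedCount} (the analytic per-reaction
#'   expectation), and \code{replicates}.
#' @examples
#' m <- generateCladeMatrix(cladeSpec(list(paste0("a", 1:5), paste0("b", 1:5))))
#' null <- randomPenetrationNull(m, replicates = 100, seed = 7)
#' null$expectedCount
#' @export
randomPenetrationNull <- function(m, replicates, seed = 1L) {
  stopifnot(is(m, "OrgMatrix"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  rt <- totalReactions(m)
  n <- nrow(m@presence)
  ri <- rowSums(m@presence)
  rxns <- reactionIds(m)

  set.seed(as.integer(seed))
  histAcc <- matrix(0, nrow = replicates, ncol = n + 1L)
  cntSum <- numeric(rt)
  cntSqSum <- numeric(rt)
  for (r in seq_len(replicates)) {
    counts <- integer(rt)
    for (i in seq_len(n)) {
      drawn <- sample.int(rt, ri[i], replace = FALSE)
      counts[drawn] <- counts[drawn] + 1L
    }
    histAcc[r, ] <- tabulate(counts + 1L, nbins = n + 1L)
    cntSum <- cntSum + counts
    cntSqSum <- cntSqSum + counts^2
  }
  histMean <- colMeans(histAcc)
  histSD <- apply(histAcc, 2L, stats::sd)
  if (replicates == 1L) histSD <- rep(0, n + 1L)
  prm <- cntSum / replicates
  prv <- pmax(cntSqSum / replicates - prm^2, 0)
  if (replicates > 1L) prv <- prv * replicates / (replicates - 1L)
  list(histMean = setNames(histMean, 0:n),
       histSD = setNames(histSD, 0:n),
       perReactionMean = setNames(prm, rxns),
       perReactionSD = setNames(sqrt(prv), rxns),
       expectedCount = sum(ri) / rt,
       replicates = replicates)
}

#' LP/HP annotation-overlap statistics
#'
#' Quantifies how disconnected the low-penetration reaction set is from the
#' high-penetration core: the fraction of LP reactions sharing no compound
#' with any HP reaction (exact set intersection against the union of all HP
#' compounds), and the fractions of LP and of HP reactions with an empty
#' pathway set.
#'
#' @param catalog a [ReactionCatalog-class] with compounds and pathways maps
#'   covering all classified reactions.
#' @param p a [PenetrationProfile-class].
#' @return list with \code{lpNoSharedCompound}, \code{lpNoPathway},
#'   \code{hpNoPathway} (fractions; NaN with a warning when the
#'   corresponding class is empty) and the supporting counts
#'   \code{nLP}, \code{nHP}.
#' @export
lpHpOverlap <- function(catalog, p) {
  stopifnot(is(catalog, "ReactionCatalog"), is(p, "PenetrationProfile"))
  lp <- names(p@classes)[p@classes == "LP"]
  hp <- names(p@classes)[p@classes == "HP"]
  classified <- c(lp, hp)
  missC <- setdiff(classified, names(catalog@compounds))
  missP <- setdiff(classified, names(catalog@pathways))
  if (length(missC) || length(missP))
    stop("missing annotation for classified reaction(s): ",
         paste(unique(c(missC, missP)), collapse = ", "))

  if (!length(lp))
    warning("no LP reactions; LP fractions are undefined (NaN)")
  if (!length(hp))
    warning("no HP reactions; HP fractions are undefined (NaN)")

  hpCompounds <- unique(unlist(catalog@compounds[hp], use.names = FALSE))
  lpNoShared <- if (length(lp)) {
    mean(vapply(lp, function(r)
      !any(catalog@compounds[[r]] %in% hpCompounds), logical(1)))
  } else NaN
  lpNoPathway <- if (length(lp)) {
    mean(lengths(catalog@pathways[lp]) == 0L)
  } else NaN
  hpNoPathway <- if (length(hp)) {
    mean(lengths(catalog@pathways[hp]) == 0L)
  } else NaN
  list(lpNoSharedCompound = lpNoShared, lpNoPathway = lpNoPathway,
       hpNoPathway = hpNoPathway, nLP = length(lp), nHP = length(hp))
}
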