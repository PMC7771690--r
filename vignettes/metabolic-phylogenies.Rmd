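---
title: "Metabolic-capability phylogenetics: models, parameters and design choices"
author: "metaphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic-capability phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaphylo)
```

## The model

`metaphylo` clusters organisms by metabolic capability. The primary data
object is an `OrgMatrix`: a binary N × R~T~ presence matrix over a reaction
catalog, with optional amino-acid sequences attached per (organism,
reaction) cell. The assumption behind the whole approach is that the
*presence* of a reaction — derived from genome annotation — is a more stable
evolutionary signal than raw sequence identity: annotation tolerates silent
and minor mutations, and a presence/absence profile is immune to
rearrangement artifacts that plague whole-genome comparisons.

Two similarity measures are provided.

**Binary fingerprints.** The Jaccard index over present-reaction sets,
computed all-to-all. It needs no sequence data, is fast, and is most
informative when the organisms span a wide taxonomic range, because it
leans on the joint distribution of rare (low-penetration) and ubiquitous
(high-penetration) reactions.

**Enzyme-sequence similarity.** When the comparison is narrowed to a small
reaction set (one pathway, a handful of functions), most binary comparisons
degenerate to all-or-nothing. The sequence mode scores each shared reaction
by exact Smith–Waterman local alignment of the catalyzing enzymes,
normalizing each raw score by the *first* sequence's self-alignment score,
so a score of 1 means "as similar to the target as to itself". Multiple
enzymes per reaction (isozymes, complex subunits) are reduced by taking the
maximum over all enzyme pairs — the most conserved pair represents the
reaction. The organism-level score is the mean over contributing reactions:
shared reactions contribute their alignment score, reactions present in
exactly one organism contribute a scalar penalty p (or are dropped in
`"ignore"` mode), and reactions absent from both organisms are always
excluded from the denominator. That exclusion is forced by the worked
example the package reproduces: with the fixture's score row
(0.87 + 0.93 + 0.75 + 0.89 = 3.44 over 4 shared + 4 one-sided reactions)
the ignore-mode mean is 3.44/4 = 0.86 and the penalty-mode means are
(3.44 + 4p)/8 — both only come out right when the three absent-from-both
reactions are excluded.

The penalty deserves a note: it is the single knob that trades binary
information (reaction content differs) against sequence information
(how conserved the shared content is). The average is affine in p with
slope (#one-sided)/n~R~, so closely related pairs — few one-sided
reactions — barely move, while distant pairs respond strongly. Negative
penalties are allowed and can drive the average negative; nothing is
clamped, and the distance transform below handles it.

## From similarity to trees

Distances are d = 1 − s, the simplest monotone map consistent with
similarities in [0, 1]; negative similarities yield distances above 1,
which UPGMA accepts unchanged. The transform is recorded in the CLI
manifest so trees are traceable to their parameters.

UPGMA is implemented in the package rather than delegated to `hclust`,
for one reason: determinism under ties. Equal-distance merges are resolved
sequentially, always merging the pair whose smallest contained leaf labels
are lexicographically smallest. Synthetic fixtures with planted clades
produce *exactly* tied within-clade distances, and a platform-dependent
tie order would make every downstream topology comparison flaky. Because
the size-weighted distance update erodes exact ties by an ulp or two,
candidate pairs within a relative 10⁻¹² of the minimum distance are treated
as tied. The test suite cross-checks the implementation against
`phangorn::upgma` on tie-free random matrices (identical clade sets and
cophenetic matrices).

Trees are `ape::phylo` objects. Every tree leaving the package passes
through canonicalization — children of each node ordered by the smallest
leaf label beneath them — giving a unique representation per topology;
mirror-image inputs serialize identically, and Newick round trips preserve
branch lengths to well below 10⁻⁹ (lengths are printed with 15 significant
digits).

## Comparing trees

The tree-similarity statistic K is the mean over leaves of a per-leaf
neighborhood score. In **binary** mode the score is 1 exactly when the
leaf's parent clade (the smallest clade containing it) has the same leaf
set in both trees — "the nearest interior branch returns the same
partition". In **weighted** mode all N − 1 internal clades of the first
tree are compared, each scaled by (N − η)/(N − 1) where η is the clade's
rank by topological (edge-count) distance from the leaf; a clade matches if
its leaf set occurs anywhere in the second tree. The normalization
(2/N) Σ~η~ (N − η)/(N − 1) = 1 guarantees K(T, T) = 1.

Two conventions here were genuinely open and are fixed as follows. First,
the rank η orders clades by edge-count distance *from the leaf* (the
"second closest" clade gets weight (N − 2)/(N − 1)), with ties broken by
the clades' smallest leaf label and then size; ordering by node height
instead would make the per-leaf score independent of the leaf, collapsing
the statistic's local resolution. Second, a clade "matches" if its leaf set
occurs anywhere in the other tree rather than at the same position,
because positions are not comparable across different topologies. Both
statistics are invariant to child order and leaf insertion order, which
the suite checks by property tests over shuffled random trees.

## Robustness to reaction noise

The sensitivity analysis asks how much mis-annotation a tree can absorb.
At noise level ζ each organism swaps part of its reaction set for uniformly
chosen absent reactions, keeping its reaction count constant — mimicking
simultaneous false-negative and false-positive annotations. Two counting
modes exist: `deterministic_round` removes exactly round(ζ·R~E~) reactions
(an organism with 1,743 reactions at ζ = 0.01 swaps exactly 17, drawn from
the catalog's absent remainder), and `bernoulli` swaps each present
reaction independently with probability ζ. The deterministic mode is the
default: it makes small-fixture tests sharp, and the two modes agree in
expectation. Within one perturbation a removed reaction cannot be re-added
(additions are drawn from the reactions absent *before* the perturbation,
without replacement).

One perturbed matrix instance feeds all pairwise comparisons of a
replicate — the noise represents a corrupted dataset, not per-pair
measurement error. The whole analysis is seeded once and is
bit-reproducible given (seed, L, ζ list, matrix). Desk-scale defaults in
the tests use L = 200 replicates on a 20-organism fixture; L is a free
parameter of `stabilityAnalysis()` and of the CLI.

## Penetration and its null model

Reaction penetration (fraction of organisms carrying a reaction) is
classified with strict outer bounds and an inclusive middle band:
LP strictly below 10%, HP strictly above 90%, MP inside [35%, 65%], and
everything else UNCLASSIFIED — reported as a residual fourth class rather
than silently merged, since the bands deliberately do not tile [0, 1].
Strictness at the bounds follows the defining phrases "less than 10%" and
"more than 90%"; a consequence worth knowing is that with N = 10 organisms
a count of 1 (fraction 0.10) is *not* LP. Reactions present in zero loaded
organisms are excluded from the profile but stay in the catalog, where the
null model can draw them.

The null model replaces each organism's reaction set by a uniform draw of
the same size from the full catalog. Its analytic per-reaction expectation
is Σ~i~ R~i~/R~T~, which the Monte-Carlo estimate matches within
3 standard errors at 1,000 replicates in the acceptance suite. The
LP/HP overlap statistics (LP reactions sharing no compound with any HP
reaction; LP/HP reactions with empty pathway sets) use exact set
intersections against the union of HP compounds, and report NaN with a
warning when a class is empty rather than inventing a 0 or 1.

## Synthetic data: what it emulates, what it does not

`generateCladeMatrix()` plants the three penetration strata the method
exploits: core reactions (every organism, HP-like), clade reactions (one
grouping each, MP-like at balanced clade sizes), and private reactions
(one organism each, LP-like). Defaults — 40 core, 15 per clade, 5 private,
chosen once as a caricature of the roughly 14% HP / 25% MP / 7% LP
per-organism composition seen in real annotation databases, with the LP
tail thinned so that desk-scale matrices stay well-conditioned.
`generateCladeSequences()` adds one root sequence per reaction (length 120,
uniform residues) and mutates it along every branch of the clade tree with
a per-site substitution probability (default 0.05, uniform over the 19
alternative residues), so within-clade sequence similarity exceeds
between-clade similarity by construction.

The generator is deliberately simple: no indels, no rate heterogeneity, no
substitution-matrix-weighted mutation, no horizontal transfer, and exact
within-stratum exchangeability (all members of a clade are equidistant).
Passing tests on these fixtures demonstrate that the pipeline recovers
planted structure and degrades monotonically under noise; they do not
demonstrate robustness to the full messiness of real annotation data —
uneven genome quality, correlated mis-annotation, or organisms with tiny
reaction networks, all of which degrade placement in practice.

## Numerical and interface choices

* Alignment scoring: BLOSUM50 with gap cost open + (k − 1)·ext for a
  length-k gap; defaults open = ext = 8, i.e. a linear cost of 8 per gap
  residue. Both parameters are exposed because "default" aligner settings
  differ between implementations. Raw scores come from
  `Biostrings::pairwiseAlignment`; the test suite verifies them to 10⁻¹²
  against an independent Gotoh dynamic-programming oracle.
* The directed normalization makes S(A, B) ≠ S(B, A) in general. Organism
  matrices are symmetrized as the mean of the two directed averages — a
  choice, recorded in the matrix's parameter metadata; both directed scores
  are kept in the per-pair score table.
* Max aggregation needs no tie-breaking (it is a max of values); the
  reported arg-pair is the lexicographically first, for provenance only.
* An organism pair with an empty joint reaction universe raises an error
  instead of scoring 0: an all-zero organism carries no information and
  UPGMA cannot place it meaningfully.
* `round()` is base R's round-half-even; at the default ζ values used here
  it never lands on .5.

## Limitations

Sequence mode is O(N² · reactions · enzymes²) exact alignments and is meant
for tens of organisms and focused reaction sets, not thousands of organisms.
UPGMA assumes a constant divergence rate (ultrametricity); no
neighbor-joining or likelihood alternative is provided, and no bootstrap
support values — robustness is quantified by the noise-injection analysis
instead. The penetration thresholds are conventions, not fitted quantities;
both they and the penalty score should be reported alongside any tree built
with the package (the CLI manifests do this automatically).
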