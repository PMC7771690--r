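# metaphylo

Phylogenetic trees from genome-scale metabolic capability.

Classical phylogenies are built from a small set of highly conserved genes.
`metaphylo` instead compares organisms by what their metabolism can *do*: the
set of biochemical reactions encoded in each genome, as recorded in an
organism–reaction presence matrix (rows = organisms, columns = reaction ids,
entries 0/1), optionally annotated with the amino-acid sequences of the
enzymes catalyzing each reaction. This view is robust to silent mutations and
annotation-level sequence drift, and it lets you zoom a comparison onto a
specific metabolic function (a pathway's reaction set) rather than a whole
genome.

## The two comparison modes

**Binary fingerprint.** For organisms A and B with reaction sets *A*, *B*,
similarity is the Jaccard index

    J(A, B) = |A ∩ B| / |A ∪ B|

computed all-to-all over the presence matrix.

**Enzyme sequences.** Each pair of enzymes for a shared reaction *R* is
scored by Smith–Waterman local alignment (BLOSUM50, linear gap cost 8),
normalized by the first sequence's self-alignment score:

    S_R(A_i, B_j) = sw(A_i, B_j) / sw(A_i, A_i)

Isozymes and complex subunits are handled by taking the maximum over all
enzyme pairs, S_R(A, B) = max_{i,j} S_R(A_i, B_j). The organism-level score
is the mean over the n_R contributing reactions,
⟨S(A,B)⟩ = (1/n_R) Σ_R S_R(A,B), where a reaction present in exactly one of
the two organisms contributes a scalar **penalty score** p (or is skipped
entirely with `penalty = "ignore"`); reactions absent from both never
contribute.

Similarities become distances via d = 1 − s and are clustered with
deterministic UPGMA into a rooted ultrametric tree with canonical
(leaf-sorted) child order, exportable as Newick.

Two trees over the same organisms are compared with a leaf-neighborhood
statistic K ∈ [0, 1]: for each leaf, score 1 if its parent clade is identical
in both trees (binary mode), or a distance-weighted average of clade matches
(weighted mode); K is the mean over leaves. A noise-injection analysis swaps
a fraction ζ of every organism's reactions for random absent ones, rebuilds
the tree L times, and reports mean K(ζ) plus per-organism placement
stability. Reaction *penetration* (the fraction of organisms carrying a
reaction) is profiled into low/medium/high classes (LP < 10%,
MP 35–65%, HP > 90%) and contrasted with a random-draw null model.

## Worked example

The package ships a two-organism toy: 11 reactions, of which A carries 7 and
B carries 5, sharing 4 (union 8).

```r
library(metaphylo)

fx <- table5Fixture()
similarityValues(pairwiseJaccard(fx$orgMatrix))
#>     A   B
#> A 1.0 0.5
#> B 0.5 1.0

treeToNewick(upgmaTree(similarityToDistance(pairwiseJaccard(fx$orgMatrix))))
#> [1] "(A:0.25,B:0.25);"
```

J(A,B) = 4/8 = 0.5, so the two leaves join at height (1 − 0.5)/2 = 0.25.
The same pair under the sequence mode, using the fixture's per-reaction
score row (four shared reactions scoring 0.87, 0.93, 0.75, 0.89 and four
one-sided reactions):

```r
sapply(list(-0.25, -0.1, 0, 0.1, 0.25, "ignore"),
       function(p) averageSimilarity(fx$scoreTable, p))
#> [1] 0.305 0.380 0.430 0.480 0.555 0.860
```

With a penalty the mean runs over n_R = 8 reactions; ignoring one-sided
reactions it runs over the 4 shared ones (3.44/4 = 0.86). A synthetic
two-clade study with 20 organisms shows the robustness analysis end to end:

```r
pairs <- function(p) lapply(seq(1, 9, 2), function(i) sprintf("%s%02d", p, c(i, i + 1)))
spec <- cladeSpec(list(pairs("a"), pairs("b")), seed = 1)
m <- generateCladeMatrix(spec)
stabilityAnalysis(m, zetas = c(0.01, 0.05, 0.2), L = 200, seed = 1)
#> StabilityReport: L = 200 replicates, deterministic_round mode, seed 1
#>   zeta = 0.01   mean K = 1.0000
#>   zeta = 0.05   mean K = 1.0000
#>   zeta = 0.2    mean K = 0.9760
```

Tree similarity to the unperturbed reference decays as the noise level
grows. A command-line wrapper with the same pipeline lives in
`inst/scripts/metaphylo` (subcommands `fingerprint-tree`, `sequence-tree`,
`compare-trees`, `sensitivity`, `penetration`, `fixtures`).

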