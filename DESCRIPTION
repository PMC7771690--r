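Package: metaphylo
Title: Metabolic-Capability Phylogenetics from Organism-Reaction Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Builds organism phylogenies from genome-scale metabolic
        reaction content. Supports binary fingerprint comparison of
        organism-reaction presence matrices via the Jaccard index, and
        enzyme-sequence comparison via self-score-normalized
        Smith-Waterman local alignments with max aggregation over
        isozymes and a configurable penalty for reactions present in
        only one organism of a pair. Similarity matrices are clustered
        with deterministic UPGMA into ultrametric trees with canonical
        leaf-sorted ordering and Newick export. Includes leaf
        neighborhood tree-similarity statistics (binary and
        distance-weighted), a noise-injection sensitivity analysis of
        tree robustness, reaction-penetration profiling (low, medium,
        high penetration classes) against a random null model, and
        deterministic clade-structured synthetic data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Biostrings, ape, jsonlite
Suggests: testthat (>= 3.0.0), withr, phangorn, igraph
Config/testthat/edition: 3
biocViews: Phylogenetics, Metabolomics, Clustering, Alignment
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alignment.R'
    'treebuild.R'
    'fixtures.R'
    'penetration.R'
    'organism-similarity.R'
    'treecompare.R'
    'jaccard.R'
    'robustness.R'
    'cli.R'
    'orgmatrix-io.R'
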