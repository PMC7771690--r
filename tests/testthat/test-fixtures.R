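test_that("the 2x11 worked-example fixture matches its printed form", {
  fx <- table5Fixture()
  p <- presence(fx$orgMatrix)
  expect_identical(unname(rowSums(p)), c(7, 5))
  shared <- colnames(p)[colSums(p) == 2]
  expect_identical(shared, c("R01", "R06", "R07", "R11"))
  expect_identical(sum(colSums(p) >= 1), 8L)  # the union of the two sets
  tab <- fx$scoreTable
  expect_identical(tab$score[tab$status == "SHARED"],
                   c(0.87, 0.93, 0.75, 0.89))
  expect_identical(sum(tab$status == "ONE_SIDED"), 4L)
  expect_identical(sum(tab$status == "ABSENT_BOTH"), 3L)
})

test_that("the 3x4 enzyme score fixture matches its printed form", {
  t6 <- table6Fixture()
  expect_identical(dim(t6), c(3L, 4L))
  expect_identical(max(t6), 0.87)
  expect_identical(min(t6), 0.23)
  expect_identical(t6["A2", "B3"], 0.23)
})

test_that("clade matrices plant the strata they promise", {
  spec <- cladeSpec(list(sprintf("a%02d", 1:5), sprintf("b%02d", 1:5)))
  m <- generateCladeMatrix(spec)
  p <- presence(m)
  expect_identical(dim(p), c(10L, 40L + 2L * 15L + 10L * 5L))
  expect_true(all(colSums(p[, startsWith(colnames(p), "CORE")]) == 10))
  expect_true(all(colSums(p[, startsWith(colnames(p), "CLADE")]) == 5))
  expect_true(all(colSums(p[, startsWith(colnames(p), "PRIV")]) == 1))
  # degenerate strata
  all1 <- generateCladeMatrix(cladeSpec(list(c("x", "y"), c("z", "w")),
                                        cladeReactions = 0L,
                                        privateReactions = 0L))
  expect_true(all(similarityValues(pairwiseJaccard(all1)) == 1))
  nocore <- generateCladeMatrix(cladeSpec(list(c("x", "y"), c("z", "w")),
                                          coreReactions = 0L,
                                          privateReactions = 0L))
  expect_identical(similarityValues(pairwiseJaccard(nocore))["x", "z"], 0)
  expect_error(cladeSpec(list(c("x", "y"), c("y", "z"))), "duplicated")
})

test_that("fingerprint UPGMA recovers the planted topology", {
  spec <- cladeSpec(list(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10)))
  m <- generateCladeMatrix(spec)
  tree <- upgmaTree(similarityToDistance(pairwiseJaccard(m)))
  expect_identical(
    treeSimilarityK(binaryTreeSimilarity(plantedTree(spec), tree)), 1)
  # nested groupings are also recovered
  nested <- acceptanceCladeSpec()
  mn <- generateCladeMatrix(nested)
  treen <- upgmaTree(similarityToDistance(pairwiseJaccard(mn)))
  expect_identical(
    treeSimilarityK(binaryTreeSimilarity(plantedTree(nested), treen)), 1)
})

test_that("fixtures are byte-identical under a fixed seed", {
  spec <- cladeSpec(list(c("a1", "a2"), c("b1", "b2")), rootLength = 25L,
                    subProb = 0.2, seed = 17L)
  m1 <- generateCladeSequences(generateCladeMatrix(spec), spec)
  m2 <- generateCladeSequences(generateCladeMatrix(spec), spec)
  expect_identical(presence(m1), presence(m2))
  expect_identical(m1@sequences, m2@sequences)
})

test_that("zero substitution probability gives identical sequences", {
  spec <- cladeSpec(list(c("a1", "a2"), c("b1", "b2")), coreReactions = 2L,
                    cladeReactions = 0L, privateReactions = 0L, subProb = 0)
  m <- generateCladeSequences(generateCladeMatrix(spec), spec)
  core1 <- vapply(organismIds(m), function(o)
    sequencesFor(m, o, "CORE001"), character(1))
  expect_identical(unname(core1), rep(core1[[1]], 4))
  expect_identical(reactionScore(core1[1], core1[3]), 1)
})

test_that("clade-correlated divergence separates within from between", {
  spec <- cladeSpec(list(sprintf("a%d", 1:3), sprintf("b%d", 1:3)),
                    coreReactions = 5L, cladeReactions = 0L,
                    privateReactions = 0L, rootLength = 80L,
                    subProb = 0.3, seed = 23L)
  m <- generateCladeSequences(generateCladeMatrix(spec), spec)
  within <- mean(vapply(reactionIds(m), function(r)
    reactionScore(sequencesFor(m, "a1", r), sequencesFor(m, "a2", r)),
    numeric(1)))
  between <- mean(vapply(reactionIds(m), function(r)
    reactionScore(sequencesFor(m, "a1", r), sequencesFor(m, "b1", r)),
    numeric(1)))
  expect_gt(within, between)
})

test_that("sequence-based UPGMA recovers the planted topology at moderate divergence", {
  spec <- cladeSpec(list(c("a1", "a2"), c("b1", "b2")), coreReactions = 6L,
                    cladeReactions = 0L, privateReactions = 0L,
                    rootLength = 60L, subProb = 0.12, seed = 29L)
  m <- generateCladeSequences(generateCladeMatrix(spec), spec)
  tree <- upgmaTree(similarityToDistance(
    pairwiseSequenceSimilarity(m, penalty = 0.25)))
  expect_identical(
    treeSimilarityK(binaryTreeSimilarity(plantedTree(spec), tree)), 1)
})
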