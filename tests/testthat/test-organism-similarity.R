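test_that("the six printed penalty-regime averages are reproduced exactly", {
  tab <- table5Fixture()$scoreTable
  # shared scores 0.87 + 0.93 + 0.75 + 0.89 = 3.44 over 4 shared + 4 one-sided
  expect_equal(averageSimilarity(tab, -0.25), 0.305, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(averageSimilarity(tab, -0.1), 0.38, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(averageSimilarity(tab, 0), 0.43, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(averageSimilarity(tab, 0.1), 0.48, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(averageSimilarity(tab, 0.25), (3.44 + 4 * 0.25) / 8,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(averageSimilarity(tab, "ignore"), 0.86, tolerance = 1e-12,
               ignore_attr = TRUE)
  # reactions absent from both organisms never contribute to n_R
  expect_identical(attr(averageSimilarity(tab, 0), "nR"), 8L)
  expect_identical(attr(averageSimilarity(tab, "ignore"), "nR"), 4L)
})

test_that("average similarity is affine in the penalty with slope k/n_R", {
  tab <- table5Fixture()$scoreTable
  base <- as.numeric(averageSimilarity(tab, 0))
  for (p in c(-0.5, -0.1, 0.3, 1)) {
    expect_equal(as.numeric(averageSimilarity(tab, p)), base + p * 4 / 8,
                 tolerance = 1e-12)
  }
  # ignore mode beats any penalty below every shared score
  expect_gt(as.numeric(averageSimilarity(tab, "ignore")),
            as.numeric(averageSimilarity(tab, 0.74)))
})

test_that("degenerate score tables behave as specified", {
  onesided <- data.frame(reaction = c("r1", "r2"),
                         status = c("ONE_SIDED", "ONE_SIDED"),
                         score = c(NA, NA))
  # a pair sharing zero reactions scores exactly the penalty
  expect_equal(as.numeric(averageSimilarity(onesided, -0.1)), -0.1)
  expect_error(averageSimilarity(onesided, "ignore"), "n_R = 0")
  absent <- data.frame(reaction = "r1", status = "ABSENT_BOTH", score = NA)
  expect_error(averageSimilarity(absent, 0.25), "n_R = 0")
})

test_that("organism similarity matches a spreadsheet-style hand summation", {
  # 6-reaction toy: 3 shared, 2 one-sided, 1 absent from both
  orgs <- c("A", "B")
  rxn <- sprintf("r%d", 1:6)
  p <- rbind(A = c(1L, 1L, 1L, 1L, 0L, 0L),
             B = c(1L, 1L, 1L, 0L, 1L, 0L))
  colnames(p) <- rxn
  set.seed(37)
  seqs <- list()
  for (org in orgs)
    for (r in rxn[p[org, ] == 1L])
      seqs[[paste(org, r, sep = "|")]] <- randomAA(25)
  m <- orgMatrix(p, sequences = seqs)
  res <- organismSimilarity(m, "A", "B", penalty = -0.1)
  shared <- vapply(rxn[1:3], function(r)
    oracleNormalizedSW(seqs[[paste0("A|", r)]], seqs[[paste0("B|", r)]]),
    numeric(1))
  expect_equal(res$score, (sum(shared) + 2 * (-0.1)) / 5, tolerance = 1e-12)
  expect_identical(res$nR, 5L)
  expect_identical(res$table$status,
                   c("SHARED", "SHARED", "SHARED", "ONE_SIDED", "ONE_SIDED",
                     "ABSENT_BOTH"))
})

test_that("a single shared reaction with identical sequences scores 1 in any mode", {
  p <- rbind(A = c(1L, 1L), B = c(1L, 0L))
  colnames(p) <- c("r1", "r2")
  seqs <- list("A|r1" = "MKVHEAGAWGHEE", "B|r1" = "MKVHEAGAWGHEE",
               "A|r2" = "MKV")
  m <- orgMatrix(p, sequences = seqs)
  expect_equal(organismSimilarity(m, "A", "B", reactionSubset = "r1",
                                  penalty = -0.25)$score, 1)
  expect_equal(organismSimilarity(m, "A", "B", reactionSubset = "r1",
                                  penalty = "ignore")$score, 1)
})

test_that("pairwise sequence similarity is symmetric and records parameters", {
  spec <- cladeSpec(list(c("a1", "a2"), c("b1", "b2")), coreReactions = 3L,
                    cladeReactions = 2L, privateReactions = 1L,
                    rootLength = 40L, subProb = 0.2, seed = 5L)
  m <- generateCladeSequences(generateCladeMatrix(spec), spec)
  s <- pairwiseSequenceSimilarity(m, penalty = 0.25)
  v <- similarityValues(s)
  expect_identical(v, t(v))
  expect_identical(unname(diag(v)), rep(1, 4))
  expect_identical(s@parameters$penaltyMode, "value")
  expect_identical(s@parameters$penaltyValue, 0.25)
  expect_identical(s@parameters$submatrix, "BLOSUM50")
  # directed averages symmetrized by their mean
  d <- organismSimilarity(m, "a1", "b1", penalty = 0.25)
  expect_equal(v["a1", "b1"], (d$score + d$scoreBA) / 2, tolerance = 1e-12)
})

test_that("identical sequences everywhere give all off-diagonal scores 1", {
  spec <- cladeSpec(list(c("a1", "a2"), c("b1", "b2")), coreReactions = 3L,
                    cladeReactions = 0L, privateReactions = 0L,
                    rootLength = 30L, subProb = 0, seed = 2L)
  m <- generateCladeSequences(generateCladeMatrix(spec), spec)
  v <- similarityValues(pairwiseSequenceSimilarity(m, penalty = 0.25))
  expect_equal(unname(v), matrix(1, 4, 4))
})

test_that("a present cell without sequences is a consistency error", {
  p <- rbind(A = c(1L, 1L), B = c(1L, 1L))
  colnames(p) <- c("r1", "r2")
  m <- orgMatrix(p, sequences = list("A|r1" = "MKV", "B|r1" = "MKV",
                                     "A|r2" = "MKV"))
  expect_error(pairwiseSequenceSimilarity(m), "B\\|r2")
  expect_error(organismSimilarity(m, "A", "B", reactionSubset = "nope"),
               "not in catalog")
})
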