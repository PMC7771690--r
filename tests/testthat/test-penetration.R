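# 10-organism toy with planted counts for threshold checks
.toyCounts <- function(counts = c(1, 5, 8, 10), n = 10) {
  rxn <- sprintf("R%02d", seq_along(counts))
  p <- matrix(0L, n, length(counts),
              dimnames = list(sprintf("o%02d", 1:n), rxn))
  # rotate each reaction's organism block so every organism carries >= 1
  for (k in seq_along(counts))
    p[(k - 1 + seq_len(counts[k]) - 1) %% n + 1, k] <- 1L
  orgMatrix(p)
}

test_that("penetration classes follow the strict/inclusive band semantics", {
  # 1/10 sits exactly on the LP bound: "less than 10%" is strict, so it is
  # unclassified, not LP
  prof <- penetrationProfile(.toyCounts())
  expect_identical(unname(penetrationClasses(prof)),
                   c("UNCLASSIFIED", "MP", "UNCLASSIFIED", "HP"))
  prof20 <- penetrationProfile(.toyCounts(c(1, 10, 16, 20), n = 20))
  expect_identical(unname(penetrationClasses(prof20)),
                   c("LP", "MP", "UNCLASSIFIED", "HP"))
  # band boundaries: == lpMax not LP, == mpLo/mpHi are MP, == hpMin not HP
  prof_b <- penetrationProfile(.toyCounts(c(2, 7, 13, 18), n = 20))
  expect_identical(unname(penetrationClasses(prof_b)),
                   c("UNCLASSIFIED", "MP", "MP", "UNCLASSIFIED"))
  expect_error(penetrationProfile(.toyCounts(), lpMax = 0.5, mpLo = 0.2),
               "thresholds")
})

test_that("a reaction in 1 of 975 organisms is LP; present in all is HP", {
  p <- matrix(0L, 975, 2, dimnames = list(sprintf("o%03d", 1:975),
                                          c("rare", "universal")))
  p[1, "rare"] <- 1L
  p[, "universal"] <- 1L
  cls <- penetrationClasses(penetrationProfile(orgMatrix(p)))
  expect_identical(unname(cls["rare"]), "LP")
  expect_identical(unname(cls["universal"]), "HP")
})

test_that("classes partition classified reactions and counts ignore N", {
  spec <- cladeSpec(list(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10)))
  m <- generateCladeMatrix(spec)
  prof <- penetrationProfile(m)
  expect_setequal(names(prof@counts),
                  colnames(presence(m))[colSums(presence(m)) > 0])
  expect_true(all(penetrationClasses(prof) %in%
                    c("LP", "MP", "HP", "UNCLASSIFIED")))
  # planted strata: core -> HP (20/20), clade -> MP (10/20), private -> LP
  cls <- penetrationClasses(prof)
  expect_true(all(cls[startsWith(names(cls), "CORE")] == "HP"))
  expect_true(all(cls[startsWith(names(cls), "CLADE")] == "MP"))
  expect_true(all(cls[startsWith(names(cls), "PRIV")] == "LP"))
})

test_that("organism composition recovers planted stratum fractions", {
  spec <- cladeSpec(list(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10)))
  m <- generateCladeMatrix(spec)
  comp <- organismComposition(m, penetrationProfile(m))
  # every organism: 40 core (HP) + 15 clade (MP) + 5 private (LP) = 60
  expect_true(all(comp$nReactions == 60))
  expect_equal(comp$HP, rep(40 / 60, 20))
  expect_equal(comp$MP, rep(15 / 60, 20))
  expect_equal(comp$LP, rep(5 / 60, 20))
  expect_equal(comp$LP + comp$MP + comp$HP + comp$UNCLASSIFIED, rep(1, 20))
})

test_that("composition edge cases behave as the thresholds dictate", {
  # all reactions shared by everyone -> HP fraction 1
  p <- matrix(1L, 3, 4, dimnames = list(c("x", "y", "z"), sprintf("R%d", 1:4)))
  comp <- organismComposition(orgMatrix(p), penetrationProfile(orgMatrix(p)))
  expect_equal(comp$HP, rep(1, 3))
  # with N = 2 every present reaction has fraction >= 0.5 -> LP impossible
  fx <- table5Fixture()$orgMatrix
  comp2 <- organismComposition(fx, penetrationProfile(fx))
  expect_equal(comp2$LP, c(0, 0))
  # mismatched matrix/profile is refused
  expect_error(organismComposition(fx, penetrationProfile(orgMatrix(p))),
               "not computed from this matrix")
})

test_that("random penetration null matches forced draws and is reproducible", {
  # every organism carries the whole catalog: the draw is forced
  p <- matrix(1L, 4, 6, dimnames = list(sprintf("o%d", 1:4), sprintf("R%d", 1:6)))
  null <- randomPenetrationNull(orgMatrix(p), replicates = 5, seed = 2)
  expect_equal(unname(null$histMean[as.character(4)]), 6)
  expect_equal(unname(null$histSD), rep(0, 5))
  expect_equal(unname(null$perReactionMean), rep(4, 6))

  m <- generateCladeMatrix(cladeSpec(list(c("a1", "a2"), c("b1", "b2"))))
  n1 <- randomPenetrationNull(m, replicates = 50, seed = 9)
  n2 <- randomPenetrationNull(m, replicates = 50, seed = 9)
  expect_identical(n1, n2)
  expect_error(randomPenetrationNull(m, replicates = 0), "replicates")
})

test_that("null histogram mass accounts for every drawn reaction", {
  m <- generateCladeMatrix(cladeSpec(list(sprintf("a%d", 1:3),
                                          sprintf("b%d", 1:3))))
  null <- randomPenetrationNull(m, replicates = 20, seed = 4)
  # counts 0..N partition the catalog in every replicate, hence on average
  expect_equal(sum(null$histMean), totalReactions(m))
})

test_that("LP/HP overlap statistics follow exact set arithmetic", {
  cat <- reactionCatalog(
    c("r1", "r2", "r3"),
    compounds = list(r1 = "C1", r2 = "C2", r3 = c("C2", "C3")),
    pathways = list(r1 = character(0), r2 = "P1", r3 = character(0)))
  # plant penetration: r1, r2 rare (LP), r3 ubiquitous (HP) among 20 organisms
  p <- matrix(0L, 20, 3, dimnames = list(sprintf("o%02d", 1:20),
                                         c("r1", "r2", "r3")))
  p[1, c("r1", "r2")] <- 1L
  p[, "r3"] <- 1L
  prof <- penetrationProfile(orgMatrix(p))
  ov <- lpHpOverlap(cat, prof)
  expect_equal(ov$lpNoSharedCompound, 0.5)   # r1 shares nothing, r2 shares C2
  expect_equal(ov$lpNoPathway, 0.5)          # r1 unassigned, r2 assigned
  expect_equal(ov$hpNoPathway, 1)            # r3 unassigned
  # missing annotation is an error naming the reaction
  cat2 <- reactionCatalog(c("r1", "r2", "r3"),
                          compounds = list(r1 = "C1", r3 = "C3"),
                          pathways = list(r1 = "P", r2 = "P", r3 = "P"))
  expect_error(lpHpOverlap(cat2, prof), "r2")
})

test_that("empty LP class yields NaN fractions with a warning", {
  p <- matrix(1L, 5, 2, dimnames = list(sprintf("o%d", 1:5), c("r1", "r2")))
  prof <- penetrationProfile(orgMatrix(p))
  cat <- reactionCatalog(c("r1", "r2"),
                         compounds = list(r1 = "C1", r2 = "C2"),
                         pathways = list(r1 = character(0),
                                         r2 = character(0)))
  expect_warning(ov <- lpHpOverlap(cat, prof), "no LP reactions")
  expect_true(is.nan(ov$lpNoSharedCompound))
  expect_true(is.nan(ov$lpNoPathway))
  expect_equal(ov$hpNoPathway, 1)
})
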