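test_that("AUC handles the canonical hand cases", {
  expect_identical(rocAUC(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_identical(rocAUC(rep(0.5, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_identical(rocAUC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(rocAUC(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC equals the brute-force pair-counting oracle on random
           instances", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    expect_lt(abs(rocAUC(scores, labels) - aucBruteForce(scores, labels)),
              1e-12)
  }
})

test_that("precision/recall/F1 match hand-computed confusion counts", {
  perfect <- precisionRecallF1(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(as.numeric(perfect), c(1, 1, 1), ignore_attr = TRUE)
  none <- precisionRecallF1(c(0.1, 0.2, 0.3), c(1, 0, 1))
  expect_equal(as.numeric(none), c(0, 0, 0), ignore_attr = TRUE)
  expect_true("precision" %in% attr(none, "degenerate"))
  # TP=5 FP=1 FN=3
  scores <- c(rep(0.9, 5), 0.9, rep(0.1, 3), rep(0.2, 4))
  labels <- c(rep(1, 5), 0, rep(1, 3), rep(0, 4))
  prf <- precisionRecallF1(scores, labels)
  expect_equal(as.numeric(prf),
               c(5 / 6, 5 / 8, 2 * (5/6) * (5/8) / (5/6 + 5/8)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(precisionRecallF1(scores, labels, threshold = 0))
})

test_that("subgroup metrics reproduce global metrics per group", {
  set.seed(14)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  one <- groupMetrics(scores, labels, rep("all", 30))
  expect_identical(one$auc, rocAUC(scores, labels))
  # disjoint duplicate groups give identical rows
  scores2 <- c(scores, scores)
  labels2 <- c(labels, labels)
  groups2 <- rep(c("a", "b"), each = 30)
  two <- groupMetrics(scores2, labels2, groups2)
  expect_identical(two$auc[1], two$auc[2])
  expect_identical(two$f1[1], two$f1[2])
  # a group missing one class gets a flagged absent AUC
  g3 <- c(rep("mixed", 29), "solo")
  labels3 <- labels; labels3[30] <- 1
  three <- groupMetrics(scores, labels3, g3)
  expect_false(three$auc_defined[three$group == "solo"])
  expect_true(is.na(three$auc[three$group == "solo"]))
})

test_that("paired bootstrap preserves pairing and degenerates correctly", {
  set.seed(15)
  sp <- generateScorePairs(60, 0.85, 0.75, seed = 4)
  # identical models: delta identically zero, equal CIs
  same <- pairedBootstrapAUC(sp$scoresA, sp$scoresA, sp$labels,
                             nBoot = 200, seed = 1)
  expect_identical(same$delta, rep(0, 200))
  expect_identical(same$ciA, same$ciB)
  # perfectly separated model: CI collapses at 1
  sep <- generateScorePairs(40, 1.0, 0.7, seed = 5)
  b <- pairedBootstrapAUC(sep$scoresA, sep$scoresB, sep$labels,
                          nBoot = 200, seed = 2)
  expect_identical(b$ciA, c(1, 1))
  # reproducible under seed
  b2 <- pairedBootstrapAUC(sep$scoresA, sep$scoresB, sep$labels,
                           nBoot = 200, seed = 2)
  expect_identical(b$delta, b2$delta)
})

test_that("permutation test matches the exhaustive oracle at n = 3 and is
           symmetric in the two models", {
  a <- c(0.9, 0.4, 0.7)
  b <- c(0.6, 0.5, 0.1)
  pExact <- permExhaustive(a, b)
  pMC <- pairedPermutationTest(a, b, nPerm = 4000, seed = 6)
  se <- sqrt(pExact * (1 - pExact) / 4000)
  expect_lt(abs(pMC - pExact), 3 * se + 2 / 4000)
  pBA <- pairedPermutationTest(b, a, nPerm = 4000, seed = 6)
  expect_identical(pMC, pBA)
  # identical scores: p = 1 exactly
  expect_identical(pairedPermutationTest(a, a, nPerm = 500, seed = 1), 1)
  expect_error(pairedPermutationTest(1, 2), "at least 2")
  # AUC-difference variant runs and returns a valid p
  sp <- generateScorePairs(30, 0.9, 0.6, seed = 7)
  pA <- pairedPermutationTest(sp$scoresA, sp$scoresB, nPerm = 300, seed = 2,
                              statistic = "auc_difference",
                              labels = sp$labels)
  expect_true(pA > 0 && pA <= 1)
})

test_that("paired Cohen's d matches the closed form and flags zero
           variance", {
  expect_identical(cohensDPaired(c(1, 0), c(0, 1))$d, 0)
  r <- cohensDPaired(c(0.1, 0.2, 0.3), c(0, 0, 0))
  expect_equal(r$d, 2.0, tolerance = 1e-12)
  const <- cohensDPaired(c(1, 1, 1), c(0.5, 0.5, 0.5))
  expect_false(const$defined)
  expect_true(is.na(const$d))
  expect_identical(const$sign, 1)
})

test_that("Monte-Carlo power recovers the test size at zero effect and
           the noncentral-t closed form on a grid", {
  p0 <- powerParametricMC(0, 1, 57, nSim = 4000, seed = 8)
  se0 <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(p0 - 0.05), 3 * se0)
  # standardized effect 2.0 at n = 57 is indistinguishable from power 1
  expect_gt(powerParametricMC(2, 1, 57, nSim = 1000, seed = 9), 0.999)
  for (eff in c(0.2, 0.5)) for (n in c(10, 30, 57)) {
    ref <- powerClosedForm(eff, 1, n)
    mc <- powerParametricMC(eff, 1, n, nSim = 3000, seed = 17)
    expect_lt(abs(mc - ref), 3 * sqrt(ref * (1 - ref) / 3000) + 1e-3)
  }
  # monotone in effect size at fixed n, sd (closed-form check of the
  # implementation's response surface)
  pows <- vapply(c(0, 0.2, 0.4, 0.8), function(e)
    powerParametricMC(e, 1, 30, nSim = 3000, seed = 21), numeric(1))
  expect_true(all(diff(pows) >= -0.02))
  expect_error(powerParametricMC(0.5, 0, 10), "positive")
})

test_that("compareModels assembles a coherent report", {
  sp <- generateScorePairs(80, 0.9, 0.75, pairingCorr = 0.6, seed = 10)
  pa <- PredictionSet(sprintf("P%02d", 1:80), pnorm(sp$scoresA), sp$labels)
  pb <- PredictionSet(sprintf("P%02d", 1:80), pnorm(sp$scoresB), sp$labels)
  rep1 <- compareModels(pa, pb, nBoot = 300, nPerm = 500, nSim = 500,
                        seed = 3)
  expect_s4_class(rep1, "ComparisonReport")
  expect_equal(rep1@aucA, rocAUC(pnorm(sp$scoresA), sp$labels))
  expect_true(rep1@ciA[1] <= rep1@aucA && rep1@aucA <= rep1@ciA[2])
  expect_true(rep1@pPermutation > 0 && rep1@pPermutation <= 1)
  expect_true(rep1@power >= 0 && rep1@power <= 1)
  rep2 <- compareModels(pa, pb, nBoot = 300, nPerm = 500, nSim = 500,
                        seed = 3)
  expect_identical(rep1@ciDelta, rep2@ciDelta)
  # identical models: p = 1 and undefined d
  repSame <- compareModels(pa, pa, nBoot = 100, nPerm = 200, nSim = 100,
                           seed = 4)
  expect_identical(repSame@pPermutation, 1)
  expect_false(repSame@cohenDefined)
  expect_identical(repSame@deltaObserved, 0)
  # misalignment errors
  pc <- PredictionSet(sprintf("Q%02d", 1:80), pnorm(sp$scoresB), sp$labels)
  expect_error(compareModels(pa, pc), "different patients")
  # reordered patients are re-aligned, not treated as misaligned
  ord <- sample(80)
  pbShuf <- PredictionSet(sprintf("P%02d", 1:80)[ord],
                          pnorm(sp$scoresB)[ord], sp$labels[ord])
  rep3 <- compareModels(pa, pbShuf, nBoot = 300, nPerm = 500, nSim = 500,
                        seed = 3)
  expect_identical(rep3@deltaObserved, rep1@deltaObserved)
  # report serializes to JSON
  path <- withr::local_tempfile(fileext = ".json")
  writeComparisonReport(rep1, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$auc_a, rep1@aucA, tolerance = 1e-12)
})
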