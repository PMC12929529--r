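mkCounts <- function(m) ExpressionMatrix(m, stage = "counts")

test_that("TPM matches the hand-evaluated formula and conserves 1e6", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "P1"))
  tpm <- exprValues(countsToTPM(mkCounts(m), geneLengths = c(1000, 2000)))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  single <- matrix(5, 1, 1, dimnames = list("g", "P1"))
  expect_equal(unname(exprValues(countsToTPM(mkCounts(single), 777))[1, 1]),
               1e6)

  set.seed(1)
  big <- matrix(rpois(300, 40), 30, 10,
                dimnames = list(sprintf("g%d", 1:30), sprintf("P%d", 1:10)))
  lens <- sample(200:5000, 30)
  out <- exprValues(countsToTPM(mkCounts(big), lens))
  expect_equal(unname(colSums(out)), rep(1e6, 10), tolerance = 1e-6)
})

test_that("TPM rejects bad input and falls back to CPM without lengths", {
  m <- matrix(c(1, 2, 0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("P1", "P2")))
  expect_error(countsToTPM(mkCounts(m), c(100, 100)), "all-zero")
  good <- m[, 1, drop = FALSE]
  expect_error(countsToTPM(mkCounts(good), c(100, 100, 100)), "match")
  expect_warning(cpm <- countsToTPM(mkCounts(good), NULL), "CPM")
  expect_equal(unname(exprValues(cpm)[, 1]), c(1, 2) / 3 * 1e6)
})

test_that("z-score normalization fits on the training split only", {
  set.seed(2)
  m <- matrix(rpois(200, 30), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("P%d", 1:10)))
  m[1, ] <- 7  # constant gene
  tpm <- countsToTPM(mkCounts(m), rep(1000, 20))
  fit <- sprintf("P%d", 1:6)
  z <- logZNormalize(tpm, fit)
  v <- exprValues(z)
  # constant gene flagged and zeroed (constant counts stay constant in TPM
  # only if library sizes match; use the recorded flag instead)
  flagged <- attr(z, "flaggedGenes")
  if (length(flagged)) expect_true(all(v[flagged, ] == 0))
  # fitted rows have mean 0, sd 1 on the fit set
  vf <- v[setdiff(rownames(v), flagged), fit]
  expect_equal(unname(rowMeans(vf)), rep(0, nrow(vf)), tolerance = 1e-12)
  expect_equal(unname(apply(vf, 1, sd)), rep(1, nrow(vf)), tolerance = 1e-12)
  # a held-out value equal to the fit mean maps to z = 0
  mu <- attr(z, "mu")
  tpmv <- exprValues(tpm)
  tpmv[, "P9"] <- 2^mu - 1
  z2 <- logZNormalize(ExpressionMatrix(tpmv, stage = "tpm"), fit)
  expect_equal(unname(exprValues(z2)[, "P9"]),
               rep(0, nrow(tpmv)), tolerance = 1e-9)
  expect_error(logZNormalize(tpm, c("nope")), "disjoint|unknown")
})

test_that("fit-all z-scores standardize every patient column set", {
  set.seed(3)
  m <- matrix(rpois(120, 50), 12, 10,
              dimnames = list(sprintf("g%d", 1:12), sprintf("P%d", 1:10)))
  tpm <- countsToTPM(mkCounts(m), rep(500, 12))
  z <- exprValues(logZNormalize(tpm, sprintf("P%d", 1:10)))
  expect_equal(unname(rowMeans(z)), rep(0, 12), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 12), tolerance = 1e-12)
})

test_that("the DE screen is well calibrated under the null", {
  set.seed(4)
  n <- 60
  m <- matrix(rnbinom(2000 * n, mu = 50, size = 2), 2000, n,
              dimnames = list(sprintf("g%d", 1:2000), sprintf("P%d", 1:n)))
  groups <- rep(c(0, 1), each = n / 2)
  de <- differentialExpression(mkCounts(m), groups)
  # KS distance to Uniform(0,1) below the 1% critical value
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(2000))
})

test_that("the DE screen recovers planted fold changes", {
  # sparse DE regime: with few DE genes the library-size composition bias
  # of median-library scaling is negligible
  sp <- syntheticSpec(nPatients = 400, prevalence = 0.5, nGenes = 1000,
                      nDeUp = 5, nDeDown = 5, deLogfc = 3,
                      bagSizeRange = c(1, 2), signalDim = 4, seed = 6)
  co <- generateCohort(sp)
  de <- differentialExpression(co@expr, cohortLabels(co))
  rownames(de) <- de$gene_id
  expect_true(all(abs(de[co@spec$deUpGenes, "logFC"] - 3) < 0.5))
  expect_true(all(abs(de[co@spec$deDownGenes, "logFC"] + 3) < 0.5))
  expect_true(all(de[c(co@spec$deUpGenes, co@spec$deDownGenes),
                     "p_value"] < 0.05))
})

test_that("DE conventions: zero genes, antisymmetry, unknown method", {
  m <- matrix(c(0, 0, 0, 0, 5, 9, 4, 8), 2, 4, byrow = TRUE,
              dimnames = list(c("zero", "g"), sprintf("P%d", 1:4)))
  groups <- c(0, 0, 1, 1)
  de <- differentialExpression(mkCounts(m), groups)
  expect_identical(de[de$gene_id == "zero", "logFC"], 0)
  expect_identical(de[de$gene_id == "zero", "p_value"], 1)
  flipped <- differentialExpression(mkCounts(m), 1 - groups)
  expect_equal(flipped$logFC, -de$logFC, tolerance = 1e-12)
  expect_error(differentialExpression(mkCounts(m), groups, method = "deseq"),
               "welch, wilcoxon")
  expect_error(differentialExpression(mkCounts(m), c(0, 0, 0, 0)),
               "non-empty")
  # wilcoxon path runs and returns probabilities
  dw <- differentialExpression(mkCounts(m), groups, method = "wilcoxon")
  expect_true(all(dw$p_value >= 0 & dw$p_value <= 1))
})

test_that("DEG selection applies strict thresholds and sorts by p", {
  toy <- data.frame(
    gene_id = sprintf("g%d", 1:5),
    logFC = c(3.1, -2.5, 2.5, -1.0, 4.0),
    p_value = c(0.01, 0.04, 0.2, 0.001, 0.049))
  sel <- selectDEGs(toy)
  expect_identical(nrow(sel$up), 2L)
  expect_identical(nrow(sel$down), 1L)
  expect_identical(sel$up$gene_id, c("g1", "g5"))   # sorted by p
  expect_identical(sel$down$gene_id, "g2")
  expect_identical(sel$table$direction,
                   c("up", "down", "ns", "ns", "up"))

  boundary <- data.frame(gene_id = "gb", logFC = 2.0, p_value = 0.01)
  selB <- suppressWarnings(selectDEGs(boundary))
  expect_identical(nrow(selB$up) + nrow(selB$down), 0L)

  empty <- toy[0, ]
  selE <- selectDEGs(empty)
  expect_identical(nrow(selE$up), 0L)
  expect_identical(nrow(selE$down), 0L)
})

test_that("feature fitting is leakage-free and supports fallback", {
  co <- smallCohort(n = 30)
  split <- patientLevelSplit(patientIds(co), seed = 2024, stratify = TRUE,
                             labels = cohortLabels(co))
  om <- suppressWarnings(fitOmicFeatures(co, trainIds(split)))
  expect_identical(om$fitPatients, trainIds(split))
  expect_identical(colnames(om$features), patientIds(co))
  expect_silent(noLeakageAudit(om, split))
  # shuffling the *test* patients' counts leaves the fitted state unchanged
  co2 <- co
  counts2 <- geneCounts(co2)
  te <- testIds(split)
  counts2[, te] <- counts2[, sample(te)]
  co2@expr <- ExpressionMatrix(counts2, stage = "counts")
  om2 <- suppressWarnings(fitOmicFeatures(co2, trainIds(split)))
  expect_identical(om2$geneIds, om$geneIds)
  expect_identical(om2$degs$table, om$degs$table)
  expect_equal(om2$features[, trainIds(split)],
               om$features[, trainIds(split)])
  # impossible thresholds engage the top-k fallback
  expect_warning(
    omF <- fitOmicFeatures(co, trainIds(split), lfcThreshold = 50,
                           fallbackK = 7),
    "fallback|top-")
  expect_identical(length(omF$geneIds), 7L)
  expect_true(omF$usedFallback)
})

test_that("count matrices and DEG tables round-trip through TSV", {
  co <- smallCohort(n = 12)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "c.tsv")
  writeCountsMatrix(co@expr, p1)
  back <- readCountsMatrix(p1)
  expect_equal(exprValues(back), geneCounts(co))
  de <- differentialExpression(co@expr, cohortLabels(co))
  p2 <- file.path(dir, "d.tsv")
  writeDEGTable(de, p2)
  expect_equal(readDEGTable(p2), de, tolerance = 1e-12)
  expect_error(readDEGTable(p1), "columns")
})
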