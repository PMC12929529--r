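test_that("Kronecker fusion reproduces the worked outer-product example", {
  expect_identical(kronFuse(c(1, 2), c(3, 4)),
                   c(3, 4, 1, 6, 8, 2, 3, 4, 1))
  # both zero: unit augmentation forces a single trailing 1
  z <- kronFuse(numeric(32), numeric(32))
  expect_identical(length(z), 1089L)
  expect_identical(z[1089], 1)
  expect_identical(sum(z != 0), 1L)
  # image-only content lands in the last column of the fused matrix
  h <- numeric(32); h[1] <- 2
  f <- kronFuse(h, numeric(32))
  M <- kronAsMatrix(f)
  expect_identical(M[1, 33], 2)
  expect_identical(M[33, 33], 1)
  expect_identical(sum(f != 0), 2L)
})

test_that("fused matrix preserves both unimodal vectors exactly
           (1000 random draws)", {
  set.seed(11)
  for (i in 1:1000) {
    h <- rnorm(32); g <- rnorm(32)
    M <- kronAsMatrix(kronFuse(h, g))
    expect_identical(M[, 33], c(h, 1))
    expect_identical(M[33, ], c(g, 1))
  }
})

test_that("concatenation fusion keeps the image block first", {
  expect_identical(concatFuse(numeric(32), numeric(32)), numeric(64))
  f <- concatFuse(1:32, 33:64)
  expect_identical(f, 1:64)
  expect_identical(length(concatFuse(rnorm(32), rnorm(32))), 64L)
})

test_that("back-projection is the stated affine map", {
  P <- backProjectionParams(9, 2, zeroInit = TRUE)
  out <- backProject(rnorm(9), P)
  expect_identical(out$hhatHistology, c(0, 0))
  expect_identical(out$hhatOmic, c(0, 0))
  P$bbh <- c(1, -2); P$bbo <- c(3, 4)
  out2 <- backProject(numeric(9), P)
  expect_identical(out2$hhatHistology, c(1, -2))
  expect_identical(out2$hhatOmic, c(3, 4))
  set.seed(2)
  P3 <- backProjectionParams(9, 2)
  f <- rnorm(9)
  expect_identical(backProject(f, P3), backProject(f, P3))
})

test_that("zeroed back-projection reduces progressive fusion to
           single-pass fusion for every T and both modes", {
  set.seed(3)
  h <- rnorm(32); g <- rnorm(32)
  for (mode in c("kron", "concat")) {
    Fdim <- if (mode == "kron") 1089L else 64L
    f0 <- if (mode == "kron") kronFuse(h, g) else concatFuse(h, g)
    for (T in 1:5) {
      cfg <- fusionConfig(mode = mode, progressive = TRUE, iterations = T)
      P <- backProjectionParams(Fdim, 32, zeroInit = TRUE)
      expect_identical(progressiveFuse(h, g, cfg, P), f0)
    }
    cfgOff <- fusionConfig(mode = mode, progressive = FALSE)
    expect_identical(progressiveFuse(h, g, cfgOff, list()), f0)
  }
})

test_that("one refinement cycle matches a hand-traced 2-d composition and
           T = 2 composes the T = 1 update twice", {
  h <- c(1, 2); g <- c(3, 4)
  set.seed(4)
  P <- list(Bh = matrix(rnorm(2 * 9, 0, 0.2), 2, 9), bbh = c(0.1, -0.1),
            Bo = matrix(rnorm(2 * 9, 0, 0.2), 2, 9), bbo = c(0.2, 0))
  cfg1 <- fusionConfig(mode = "kron", iterations = 1, unimodalDim = 2)
  # independent scalar trace: fuse -> project -> add -> fuse
  f0 <- as.vector(outer(c(g, 1), c(h, 1)))
  hh <- as.vector(P$Bh %*% f0) + P$bbh
  gh <- as.vector(P$Bo %*% f0) + P$bbo
  fRef <- as.vector(outer(c(g + gh, 1), c(h + hh, 1)))
  expect_equal(progressiveFuse(h, g, cfg1, P), fRef, tolerance = 1e-12)
  # compositionality with shared weights
  hh2 <- as.vector(P$Bh %*% fRef) + P$bbh
  gh2 <- as.vector(P$Bo %*% fRef) + P$bbo
  fRef2 <- as.vector(outer(c(g + gh2, 1), c(h + hh2, 1)))
  cfg2 <- fusionConfig(mode = "kron", iterations = 2, unimodalDim = 2)
  expect_equal(progressiveFuse(h, g, cfg2, P), fRef2, tolerance = 1e-12)
  expect_error(fusionConfig(iterations = 6), "1..5")
  expect_error(fusionConfig(iterations = 0), "1..5")
})

test_that("unimodal heads are ReLU-gated and reject a DEG index mismatch", {
  params <- list(Wih = matrix(0, 32, 512), bih = numeric(32),
                 Wo1 = matrix(0, 128, 10), bo1 = numeric(128),
                 Wo2 = matrix(0, 32, 128), bo2 = numeric(32))
  out <- unimodalHeads(rnorm(512), rnorm(10), params)
  expect_identical(out$hHistology, numeric(32))
  expect_identical(out$hOmic, numeric(32))
  params$bih <- rep(-1, 32)
  expect_identical(unimodalHeads(rnorm(512), rnorm(10),
                                 params)$hHistology, numeric(32))
  expect_error(unimodalHeads(rnorm(512), rnorm(4), params), "DEG")
  set.seed(5)
  p2 <- list(Wih = matrix(rnorm(32 * 512, 0, 0.05), 32, 512),
             bih = rnorm(32),
             Wo1 = matrix(rnorm(128 * 10, 0, 0.3), 128, 10),
             bo1 = rnorm(128),
             Wo2 = matrix(rnorm(32 * 128, 0, 0.2), 32, 128),
             bo2 = rnorm(32))
  o1 <- unimodalHeads(rep(0.1, 512), rep(0.2, 10), p2)
  o2 <- unimodalHeads(rep(0.1, 512), rep(0.2, 10), p2)
  expect_identical(o1, o2)
  expect_true(all(o1$hHistology >= 0) && all(o1$hOmic >= 0))
})

test_that("classifier head saturates correctly and is deterministic in
           evaluation mode", {
  zeroP <- list(Wc = matrix(0, 4, 9), bc = numeric(4),
                wc = numeric(4), bc2 = 0)
  expect_identical(classifyFused(rnorm(9), zeroP), 0.5)
  satP <- zeroP; satP$bc2 <- 20
  expect_gt(classifyFused(rnorm(9), satP), 0.999)
  set.seed(6)
  P <- list(Wc = matrix(rnorm(36), 4, 9), bc = rnorm(4),
            wc = rnorm(4), bc2 = 0.3)
  f <- rnorm(9)
  expect_identical(classifyFused(f, P, train = FALSE),
                   classifyFused(f, P, train = FALSE))
})

test_that("late fusion is the stated convex combination", {
  expect_identical(lateFusion(0.3, 0.9, w = 1), 0.3)
  expect_identical(lateFusion(0.7, 0.7, w = 0.123), 0.7)
  expect_equal(lateFusion(0.2, 0.9, w = 0.3), 0.69, tolerance = 1e-12)
  expect_error(lateFusion(0.5, 0.5, w = 1.2), "\\[0, 1\\]")
})

test_that("DMLP outputs calibrated probabilities and trains to separate a
           separable toy problem", {
  zeroP <- list(W1 = matrix(0, 8, 2), b1 = numeric(8),
                W2 = matrix(0, 4, 8), b2 = numeric(4),
                w3 = numeric(4), b3 = 0)
  expect_identical(dmlpForward(c(1, -1), zeroP), 0.5)
  set.seed(7)
  P <- list(W1 = matrix(rnorm(16), 8, 2), b1 = rnorm(8),
            W2 = matrix(rnorm(32), 4, 8), b2 = rnorm(4),
            w3 = rnorm(4), b3 = 0)
  expect_identical(dmlpForward(c(1, 2), P, train = FALSE),
                   dmlpForward(c(1, 2), P, train = FALSE))
  # logistic separability: a linearly separable 2-feature cohort reaches
  # training accuracy 1 after convergence
  co <- smallCohort(n = 40)
  ids <- patientIds(co)
  labs <- cohortLabels(co)
  feat <- rbind(ifelse(labs == 1, 2, -2) + rnorm(40, 0, 0.1),
                ifelse(labs == 1, -1.5, 1.5) + rnorm(40, 0, 0.1))
  dimnames(feat) <- list(c("fa", "fb"), ids)
  om <- structure(list(features = feat, geneIds = c("fa", "fb"),
                       fitPatients = ids, usedFallback = FALSE,
                       degs = list(up = NULL, down = NULL)),
                  class = "OmicFeatures")
  asg <- setNames(rep("train", 40), ids)
  split <- new("SplitAssignment",
               assignment = factor(asg, levels = c("train", "val", "test")),
               ratio = c(1, 0, 0), seed = 1L)
  run <- trainModel(co, split, "DMLP",
                    trainConfig(epochs = 60, learningRate = 1e-2,
                                dropout = 0, seed = 1), om)
  acc <- mean((predScores(run$predictions$train) >= 0.5) == (labs == 1))
  expect_identical(acc, 1)
})

test_that("analytic gradients match finite differences for every head", {
  fw <- kronmil:::.forwardModel
  bw <- kronmil:::.backwardModel
  bce <- kronmil:::.bce
  set.seed(42)
  X <- matrix(rnorm(5 * 2048), 5, 2048)
  xo <- rnorm(12)
  configs <- list(
    AMIL = fusionConfig(),
    DMLP = fusionConfig(),
    MMF_Con = fusionConfig(),
    ProMMF_Kron = fusionConfig(iterations = 3),
    ProMMF_Kron_periter = fusionConfig(iterations = 2,
                                       shareBackprojectionWeights = FALSE))
  for (key in names(configs)) {
    nm <- sub("_periter", "", key)
    model <- buildModel(nm, omicDim = 12, config = configs[[key]])
    f0 <- fw(model, X, xo, train = FALSE)
    grads <- bw(model, f0$cache, f0$p - 1)
    for (pn in names(model$params)) {
      expect_false(is.null(grads[[pn]]), info = paste(key, pn))
      idx <- sample(length(model$params[[pn]]),
                    min(3, length(model$params[[pn]])))
      for (i in idx) {
        eps <- 1e-5
        m2 <- model
        m2$params[[pn]][i] <- m2$params[[pn]][i] + eps
        lp <- bce(fw(m2, X, xo, FALSE)$p, 1)
        m2$params[[pn]][i] <- m2$params[[pn]][i] - 2 * eps
        lm <- bce(fw(m2, X, xo, FALSE)$p, 1)
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - grads[[pn]][i]) /
                    max(1e-4, abs(num) + abs(grads[[pn]][i])),
                  1e-4)
      }
    }
  }
})

test_that("gradient flows into every parameter group of the progressive
           fusion model", {
  set.seed(9)
  model <- buildModel("ProMMF_Kron", omicDim = 12)
  X <- matrix(rnorm(6 * 2048), 6, 2048)
  xo <- rnorm(12)
  fw <- kronmil:::.forwardModel(model, X, xo, train = FALSE)
  gr <- kronmil:::.backwardModel(model, fw$cache, fw$p - 1)
  for (pn in names(model$params))
    expect_gt(sum(abs(gr[[pn]])), 0)
  expect_gt(fw$p, 0)
  expect_lt(fw$p, 1)
})

test_that("checkpoints round-trip through JSON", {
  set.seed(10)
  model <- buildModel("ProMMF_Con", omicDim = 5,
                      config = fusionConfig(iterations = 2))
  path <- withr::local_tempfile(fileext = ".json")
  saveCheckpoint(model, path, seed = 99)
  back <- loadCheckpoint(path)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_identical(back$seed, 99L)
  X <- matrix(rnorm(3 * 2048), 3, 2048)
  xo <- rnorm(5)
  expect_equal(kronmil:::.forwardModel(back, X, xo)$p,
               kronmil:::.forwardModel(model, X, xo)$p, tolerance = 1e-12)
})
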