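# Model zoo: constructors, forward passes with caches, and analytic
# backward passes. Parameters live in flat named lists so the Adam kernel
# can walk them; gradients mirror the parameter names exactly (verified by
# finite-difference checks in the test suite).

#' Registered model names
#'
#' The seven heads the package trains and compares: unimodal attention-MIL
#' on images (`AMIL`), unimodal expression MLP (`DMLP`), decision-level
#' `LateFusion`, single-pass intermediate fusion (`MMF_Kron`, `MMF_Con`),
#' and progressive back-projection fusion (`ProMMF_Kron`, `ProMMF_Con`).
#'
#' @return character vector of model names.
#' @export
modelRegistry <- function() {
  c("AMIL", "DMLP", "LateFusion", "MMF_Kron", "MMF_Con",
    "ProMMF_Kron", "ProMMF_Con")
}

.fusionSpecFromName <- function(name) {
  switch(name,
    MMF_Kron    = list(mode = "kron",   progressive = FALSE),
    MMF_Con     = list(mode = "concat", progressive = FALSE),
    ProMMF_Kron = list(mode = "kron",   progressive = TRUE),
    ProMMF_Con  = list(mode = "concat", progressive = TRUE),
    NULL)
}

#' Build a model
#'
#' Initializes parameters for one registered model. Weights are Glorot
#' uniform, biases zero; draws come from the current RNG stream, so a
#' `set.seed()` before the call makes initialization reproducible. For the
#' fusion models the `mode`/`progressive` fields of `config` are overridden
#' by the model name.
#'
#' @param name one of [modelRegistry()] (except `LateFusion`, which is a
#'   combination of trained `AMIL` and `DMLP` models, not a parameter set).
#' @param omicDim length of the DEG-indexed molecular feature vector.
#' @param config a [fusionConfig()].
#' @param embedDim,projDim,attnDim image-branch dimensions
#'   (2048 -> 512, attention hidden 256).
#' @param dmlpHidden DMLP hidden sizes (128 then 32).
#' @return list with `name`, `type`, `config`, dimension fields and
#'   `params`.
#' @export
buildModel <- function(name, omicDim = NULL, config = fusionConfig(),
                       embedDim = 2048L, projDim = 512L, attnDim = 256L,
                       dmlpHidden = c(128L, 32L)) {
  stopifnot(name %in% modelRegistry())
  if (name == "LateFusion")
    stop("LateFusion is trained via trainModel(), which fits its two ",
         "unimodal components; it has no standalone parameter set")
  d <- config$unimodalDim
  model <- list(name = name, config = config, embedDim = embedDim,
                projDim = projDim, attnDim = attnDim, omicDim = omicDim)
  if (name == "AMIL") {
    model$type <- "amil"
    model$params <- c(
      gatedAttentionParams(attnDim, embedDim, projDim),
      list(Wh = .glorot(d, projDim), bh = numeric(d),
           wo = as.vector(.glorot(d, 1L)), bo = 0))
  } else if (name == "DMLP") {
    stopifnot(!is.null(omicDim))
    model$type <- "dmlp"
    model$params <- list(
      W1 = .glorot(dmlpHidden[1], omicDim), b1 = numeric(dmlpHidden[1]),
      W2 = .glorot(dmlpHidden[2], dmlpHidden[1]), b2 = numeric(dmlpHidden[2]),
      w3 = as.vector(.glorot(dmlpHidden[2], 1L)), b3 = 0)
  } else {
    stopifnot(!is.null(omicDim))
    fs <- .fusionSpecFromName(name)
    config$mode <- fs$mode
    config$progressive <- fs$progressive
    model$config <- config
    Fdim <- .fusedDim(d, config$mode)
    params <- c(
      gatedAttentionParams(attnDim, embedDim, projDim),
      list(Wih = .glorot(d, projDim), bih = numeric(d),
           Wo1 = .glorot(128L, omicDim), bo1 = numeric(128L),
           Wo2 = .glorot(d, 128L), bo2 = numeric(d)))
    if (config$progressive) {
      nSlots <- if (config$shareBackprojectionWeights) 1L
                else config$iterations
      for (s in seq_len(nSlots)) {
        bp <- backProjectionParams(Fdim, d)
        names(bp) <- paste0(names(bp), if (nSlots == 1L) "" else s)
        params <- c(params, bp)
      }
    }
    params <- c(params, list(
      Wc = .glorot(config$classifierHidden, Fdim),
      bc = numeric(config$classifierHidden),
      wc = as.vector(.glorot(config$classifierHidden, 1L)), bc2 = 0))
    model$type <- "fusion"
    model$fusedDim <- Fdim
    model$params <- params
  }
  model
}

# extract the back-projection parameter list from flat fusion params
.backParamsOf <- function(model) {
  cfg <- model$config
  if (!cfg$progressive) return(list())
  if (cfg$shareBackprojectionWeights) {
    p <- model$params
    list(list(Bh = p$Bh, bbh = p$bbh, Bo = p$Bo, bbo = p$bbo))
  } else {
    lapply(seq_len(cfg$iterations), function(s) {
      p <- model$params
      list(Bh = p[[paste0("Bh", s)]], bbh = p[[paste0("bbh", s)]],
           Bo = p[[paste0("Bo", s)]], bbo = p[[paste0("bbo", s)]])
    })
  }
}

## ---- shared attention branch ----

.attnForward <- function(X, p, dropout, train) {
  pre <- sweep(tcrossprod(X, p$Wp), 2, p$bp, "+")
  maskH <- matrix(.dropoutMask(length(pre), dropout, train),
                  nrow(pre), ncol(pre))
  H <- pmax(pre, 0) * maskH
  Tm <- tanh(tcrossprod(H, p$Va))
  Sm <- .sigmoid(tcrossprod(H, p$Ua))
  G <- Tm * Sm
  l <- as.vector(G %*% p$wa)
  l <- l - max(l)
  e <- exp(l)
  A <- e / sum(e)
  list(X = X, pre = pre, maskH = maskH, H = H, Tm = Tm, Sm = Sm, G = G,
       A = A, hPatient = as.vector(crossprod(H, A)))
}

.attnBackward <- function(cc, p, dhp) {
  dA <- as.vector(cc$H %*% dhp)
  dH <- outer(cc$A, dhp)
  dl <- cc$A * (dA - sum(cc$A * dA))
  dG <- outer(dl, p$wa)
  dwa <- as.vector(crossprod(cc$G, dl))
  dTm <- dG * cc$Sm
  dSm <- dG * cc$Tm
  dPV <- dTm * (1 - cc$Tm^2)
  dPU <- dSm * cc$Sm * (1 - cc$Sm)
  dH <- dH + dPV %*% p$Va + dPU %*% p$Ua
  dpre <- (dH * cc$maskH) * (cc$pre > 0)
  list(Wp = crossprod(dpre, cc$X), bp = colSums(dpre),
       Va = crossprod(dPV, cc$H), Ua = crossprod(dPU, cc$H), wa = dwa)
}

## ---- per-model forward/backward ----

.forwardAMIL <- function(model, X, train) {
  p <- model$params
  dr <- model$config$dropout
  att <- .attnForward(X, p, dr, train)
  z <- as.vector(p$Wh %*% att$hPatient) + p$bh
  mz <- .dropoutMask(length(z), dr, train)
  r <- pmax(z, 0) * mz
  logit <- sum(p$wo * r) + p$bo
  list(p = .sigmoid(logit), logit = logit,
       cache = list(att = att, z = z, mz = mz, r = r))
}

.backwardAMIL <- function(model, cache, dlogit) {
  p <- model$params
  g <- list(wo = dlogit * cache$r, bo = dlogit)
  dz <- (dlogit * p$wo) * cache$mz * (cache$z > 0)
  g$Wh <- outer(dz, cache$att$hPatient)
  g$bh <- dz
  dhp <- as.vector(crossprod(p$Wh, dz))
  c(g, .attnBackward(cache$att, p, dhp))
}

.forwardDMLP <- function(model, x, train) {
  p <- model$params
  dr <- model$config$dropout
  z1 <- as.vector(p$W1 %*% x) + p$b1
  m1 <- .dropoutMask(length(z1), dr, train)
  r1 <- pmax(z1, 0) * m1
  z2 <- as.vector(p$W2 %*% r1) + p$b2
  m2 <- .dropoutMask(length(z2), dr, train)
  r2 <- pmax(z2, 0) * m2
  logit <- sum(p$w3 * r2) + p$b3
  list(p = .sigmoid(logit), logit = logit,
       cache = list(x = x, z1 = z1, m1 = m1, r1 = r1,
                    z2 = z2, m2 = m2, r2 = r2))
}

.backwardDMLP <- function(model, cache, dlogit) {
  p <- model$params
  g <- list(w3 = dlogit * cache$r2, b3 = dlogit)
  dz2 <- (dlogit * p$w3) * cache$m2 * (cache$z2 > 0)
  g$W2 <- outer(dz2, cache$r1)
  g$b2 <- dz2
  dz1 <- as.vector(crossprod(p$W2, dz2)) * cache$m1 * (cache$z1 > 0)
  g$W1 <- outer(dz1, cache$x)
  g$b1 <- dz1
  g
}

.forwardFusion <- function(model, X, x, train) {
  p <- model$params
  cfg <- model$config
  dr <- cfg$dropout
  att <- .attnForward(X, p, dr, train)
  zh <- as.vector(p$Wih %*% att$hPatient) + p$bih
  h <- pmax(zh, 0)
  z1 <- as.vector(p$Wo1 %*% x) + p$bo1
  m1 <- .dropoutMask(length(z1), dr, train)
  r1 <- pmax(z1, 0) * m1
  z2 <- as.vector(p$Wo2 %*% r1) + p$bo2
  g <- pmax(z2, 0)
  bp <- .backParamsOf(model)
  core <- .progressiveCore(h, g, cfg$mode, cfg$progressive, cfg$iterations,
                           bp, cfg$shareBackprojectionWeights, cache = TRUE)
  zc <- as.vector(p$Wc %*% core$f) + p$bc
  mc <- .dropoutMask(length(zc), dr, train)
  rc <- pmax(zc, 0) * mc
  logit <- sum(p$wc * rc) + p$bc2
  list(p = .sigmoid(logit), logit = logit,
       cache = list(att = att, zh = zh, h = h, x = x, z1 = z1, m1 = m1,
                    r1 = r1, z2 = z2, g = g, core = core, bp = bp,
                    zc = zc, mc = mc, rc = rc))
}

.backwardFusion <- function(model, cache, dlogit) {
  p <- model$params
  cfg <- model$config
  gr <- list(wc = dlogit * cache$rc, bc2 = dlogit)
  dzc <- (dlogit * p$wc) * cache$mc * (cache$zc > 0)
  gr$Wc <- outer(dzc, cache$core$f)
  gr$bc <- dzc
  df <- as.vector(crossprod(p$Wc, dzc))
  pb <- .progressiveBackward(df, cache$h, cache$g, cfg$mode,
                             cfg$progressive, cfg$iterations, cache$bp,
                             cfg$shareBackprojectionWeights, cache$core)
  if (cfg$progressive) {
    nSlots <- if (cfg$shareBackprojectionWeights) 1L else cfg$iterations
    for (s in seq_len(nSlots)) {
      sfx <- if (nSlots == 1L) "" else as.character(s)
      gr[[paste0("Bh", sfx)]] <- pb$dB[[s]]$Bh
      gr[[paste0("bbh", sfx)]] <- pb$dB[[s]]$bbh
      gr[[paste0("Bo", sfx)]] <- pb$dB[[s]]$Bo
      gr[[paste0("bbo", sfx)]] <- pb$dB[[s]]$bbo
    }
  }
  dzh <- pb$dh * (cache$zh > 0)
  gr$Wih <- outer(dzh, cache$att$hPatient)
  gr$bih <- dzh
  dhp <- as.vector(crossprod(p$Wih, dzh))
  dz2 <- pb$dg * (cache$z2 > 0)
  gr$Wo2 <- outer(dz2, cache$r1)
  gr$bo2 <- dz2
  dz1 <- as.vector(crossprod(p$Wo2, dz2)) * cache$m1 * (cache$z1 > 0)
  gr$Wo1 <- outer(dz1, cache$x)
  gr$bo1 <- dz1
  c(gr, .attnBackward(cache$att, p, dhp))
}

# unified single-patient step interface
.forwardModel <- function(model, X, x, train = FALSE) {
  switch(model$type,
         amil = .forwardAMIL(model, X, train),
         dmlp = .forwardDMLP(model, x, train),
         fusion = .forwardFusion(model, X, x, train),
         stop("unknown model type"))
}

.backwardModel <- function(model, cache, dlogit) {
  switch(model$type,
         amil = .backwardAMIL(model, cache, dlogit),
         dmlp = .backwardDMLP(model, cache, dlogit),
         fusion = .backwardFusion(model, cache, dlogit))
}

#' Predict MSI probabilities for a set of patients
#'
#' Runs a trained model in evaluation mode (dropout disabled, fully
#' deterministic) over the named patients of a cohort.
#'
#' @param model a trained model (from [trainModel()]'s `$model`, or
#'   [buildModel()] for an untrained one), or a late-fusion composite.
#' @param cohort a [MultiModalCohort-class].
#' @param ids patient ids to score.
#' @param omicFeatures an `OmicFeatures` object ([fitOmicFeatures()]);
#'   required for models with a molecular branch.
#' @return A [PredictionSet-class].
#' @export
predictModel <- function(model, cohort, ids, omicFeatures = NULL) {
  ids <- as.character(ids)
  if (identical(model$type, "late")) {
    pa <- predScores(predictModel(model$amil, cohort, ids))
    po <- predScores(predictModel(model$dmlp, cohort, ids, omicFeatures))
    return(PredictionSet(ids, lateFusion(pa, po, model$w),
                         cohortLabels(cohort)[ids]))
  }
  needOmic <- model$type %in% c("dmlp", "fusion")
  if (needOmic && is.null(omicFeatures))
    stop("omicFeatures required for model ", model$name)
  scores <- vapply(ids, function(id) {
    X <- if (model$type != "dmlp") tileBag(cohort, id) else NULL
    x <- if (needOmic) omicVector(omicFeatures, id) else NULL
    .forwardModel(model, X, x, train = FALSE)$p
  }, numeric(1))
  PredictionSet(ids, unname(scores), cohortLabels(cohort)[ids])
}

#' Save / load a model checkpoint
#'
#' Plain-text (JSON) checkpoint carrying the parameter tensors, the
#' configuration snapshot and the training seed.
#'
#' @param model a model list.
#' @param path output `.json` path.
#' @param seed optional training seed to record.
#' @export
saveCheckpoint <- function(model, path, seed = NULL) {
  obj <- model
  obj$config <- unclass(model$config)
  obj$params <- lapply(model$params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
    else list(dim = NULL, data = as.vector(p))
  })
  obj$seed <- seed
  obj$package_version <- as.character(packageVersion("kronmil"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else if (length(p$data) == 1L) p$data else as.numeric(p$data)
  })
  if (!is.null(obj$config)) {
    cfgNames <- names(formals(fusionConfig))
    cfg <- obj$config[intersect(names(obj$config), cfgNames)]
    restored <- do.call(fusionConfig, cfg)
    restored$mode <- obj$config$mode
    restored$progressive <- isTRUE(obj$config$progressive)
    obj$config <- restored
  }
  obj
}
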