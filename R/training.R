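#' Training configuration
#'
#' The optimization protocol: Adam with learning rate 1e-4 and weight
#' decay 5e-3, binary cross entropy loss, 100 epochs, batch size fixed to
#' 1 (bags differ in size, so one patient's image and molecular features
#' are drawn together per step), dropout 0.1.
#'
#' @param learningRate Adam learning rate.
#' @param weightDecay L2 weight decay added to the gradient.
#' @param epochs training epochs.
#' @param batchSize must be 1.
#' @param dropout dropout rate, copied into the fusion config.
#' @param fusion a [fusionConfig()].
#' @param seed integer; every source of training randomness
#'   (initialization, epoch shuffles, dropout, tile subsampling) derives
#'   from it.
#' @param maxTiles optional per-step cap on tiles drawn from a bag
#'   (`NULL` = use the whole bag).
#' @return validated list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 1e-4, weightDecay = 5e-3,
                        epochs = 100L, batchSize = 1L, dropout = 0.1,
                        fusion = fusionConfig(), seed = 1L,
                        maxTiles = NULL) {
  stopifnot(learningRate > 0, weightDecay >= 0, epochs >= 1)
  if (batchSize != 1L)
    stop("batch size is fixed to 1 (bags have different sizes)")
  fusion$dropout <- dropout
  structure(list(learningRate = learningRate, weightDecay = weightDecay,
                 epochs = as.integer(epochs), batchSize = 1L,
                 dropout = dropout, fusion = fusion,
                 seed = as.integer(seed),
                 maxTiles = if (is.null(maxTiles)) NULL
                            else as.integer(maxTiles)),
            class = "TrainConfig")
}

#' Patient-level train/val/test split
#'
#' Shuffles patient ids under the seed and assigns the first
#' `floor(0.6 n)` to train, the next `floor(0.2 n)` to val, and the
#' remainder to test (floor/floor/remainder, documented because cohort
#' sizes are rarely divisible 6:2:2 -- 282 patients give 169/56/57).
#' Splitting at the patient level means every tile and the expression
#' profile of a patient inherit one fold, preventing leakage across
#' splits. Plain random splitting is the default; `stratify = TRUE`
#' applies the same rule within each class (useful for small synthetic
#' cohorts).
#'
#' @param ids patient ids (>= 5).
#' @param ratio length-3 split ratio summing to 1.
#' @param seed integer seed (2024 is the protocol default).
#' @param stratify split within class strata.
#' @param labels named binary labels, required when `stratify = TRUE`.
#' @return A [SplitAssignment-class].
#' @export
patientLevelSplit <- function(ids, ratio = c(0.6, 0.2, 0.2), seed = 2024L,
                              stratify = FALSE, labels = NULL) {
  ids <- as.character(ids)
  stopifnot(length(ids) >= 5L, !anyDuplicated(ids))
  if (abs(sum(ratio) - 1) > 1e-8) stop("ratio must sum to 1")
  set.seed(as.integer(seed))
  assignOne <- function(v) {
    v <- sample(v)
    n <- length(v)
    nTrain <- floor(ratio[1] * n)
    nVal <- floor(ratio[2] * n)
    out <- rep("test", n)
    out[seq_len(nTrain)] <- "train"
    if (nVal > 0) out[nTrain + seq_len(nVal)] <- "val"
    setNames(out, v)
  }
  asg <- if (stratify) {
    stopifnot(!is.null(labels))
    do.call(c, unname(lapply(split(ids, labels[ids]), assignOne)))
  } else assignOne(ids)
  new("SplitAssignment",
      assignment = factor(asg[ids], levels = c("train", "val", "test")),
      ratio = as.numeric(ratio), seed = as.integer(seed))
}

#' Train one model with the fixed optimization protocol
#'
#' Per step one training patient is sampled (epoch-wise shuffle) and the
#' patient's image bag and molecular features are fed together; the BCE
#' loss gradient drives one Adam update. Per epoch the mean training loss
#' and the validation AUC are recorded; the checkpoint with the best
#' validation AUC is kept (ties resolve to the earlier epoch; if the
#' validation AUC is undefined the final epoch is used). All randomness
#' derives from `config$seed`, so two runs with the same inputs produce
#' bit-identical loss histories.
#'
#' @param cohort a [MultiModalCohort-class].
#' @param split a [SplitAssignment-class] over the cohort's patients.
#' @param modelName one of [modelRegistry()].
#' @param config a [trainConfig()].
#' @param omicFeatures an `OmicFeatures` fitted on the training split
#'   (required for models with a molecular branch); [noLeakageAudit()] is
#'   run on it.
#' @return list of class `TrainRun`: `history` (epoch, train_loss,
#'   val_auc), `bestEpoch`, `model` (best checkpoint), `predictions`
#'   (train/val/test [PredictionSet-class]s), `config`.
#' @export
trainModel <- function(cohort, split, modelName, config = trainConfig(),
                       omicFeatures = NULL) {
  stopifnot(is(cohort, "MultiModalCohort"), is(split, "SplitAssignment"),
            inherits(config, "TrainConfig"))
  if (!modelName %in% modelRegistry())
    stop("unknown model '", modelName, "'; available: ",
         paste(modelRegistry(), collapse = ", "))
  tr <- trainIds(split)
  labs <- cohortLabels(cohort)
  if (length(unique(labs[tr])) < 2L)
    stop("training split contains a single class")

  if (modelName == "LateFusion")
    return(.trainLateFusion(cohort, split, config, omicFeatures))

  needOmic <- modelName != "AMIL"
  if (needOmic) {
    if (is.null(omicFeatures)) stop("omicFeatures required for ", modelName)
    noLeakageAudit(omicFeatures, split)
  }

  set.seed(config$seed)
  model <- buildModel(modelName,
                      omicDim = if (needOmic) nrow(omicFeatures$features),
                      config = config$fusion)
  model$config$dropout <- config$dropout
  state <- .adamInit(model$params)
  # private working copy: the Adam kernel updates tensors in place
  model$params <- .copyParams(model$params)

  va <- valIds(split)
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = NA_real_, val_auc = NA_real_)
  best <- list(auc = -Inf, epoch = NA_integer_, params = NULL)

  evalScores <- function(ids) {
    vapply(ids, function(id) {
      X <- if (model$type != "dmlp") tileBag(cohort, id) else NULL
      x <- if (needOmic) omicVector(omicFeatures, id) else NULL
      .forwardModel(model, X, x, train = FALSE)$p
    }, numeric(1))
  }

  for (epoch in seq_len(config$epochs)) {
    order <- sample(tr)
    lossSum <- 0
    for (id in order) {
      X <- if (model$type != "dmlp") {
        bag <- tileBag(cohort, id)
        if (!is.null(config$maxTiles) && nrow(bag) > config$maxTiles)
          bag[sample.int(nrow(bag), config$maxTiles), , drop = FALSE]
        else bag
      } else NULL
      x <- if (needOmic) omicVector(omicFeatures, id) else NULL
      y <- labs[[id]]
      fw <- .forwardModel(model, X, x, train = TRUE)
      lossSum <- lossSum + .bce(fw$p, y)
      grads <- .backwardModel(model, fw$cache, fw$p - y)
      state <- .adamStep(model$params, grads, state,
                         config$learningRate, config$weightDecay)
    }
    history$train_loss[epoch] <- lossSum / length(tr)
    if (length(va)) {
      aucV <- tryCatch(rocAUC(evalScores(va), labs[va]),
                       error = function(e) NA_real_)
      history$val_auc[epoch] <- aucV
      if (!is.na(aucV) && aucV > best$auc) {
        best <- list(auc = aucV, epoch = epoch,
                     params = .copyParams(model$params))
      }
    }
  }
  if (is.null(best$params)) {
    best <- list(auc = NA_real_, epoch = config$epochs,
                 params = .copyParams(model$params))
  }
  model$params <- best$params

  preds <- lapply(list(train = tr, val = va, test = testIds(split)),
                  function(ids) {
                    if (!length(ids)) return(NULL)
                    predictModel(model, cohort, ids, omicFeatures)
                  })
  structure(list(modelName = modelName, history = history,
                 bestEpoch = best$epoch, model = model,
                 predictions = preds, config = config),
            class = "TrainRun")
}

.trainLateFusion <- function(cohort, split, config, omicFeatures) {
  cfgA <- config; cfgA$seed <- config$seed
  cfgD <- config; cfgD$seed <- config$seed + 1L
  runA <- trainModel(cohort, split, "AMIL", cfgA)
  runD <- trainModel(cohort, split, "DMLP", cfgD, omicFeatures)
  w <- config$fusion$lateFusionWeight
  va <- valIds(split)
  if (config$fusion$tuneLateWeight && length(va)) {
    labs <- cohortLabels(cohort)[va]
    pa <- predScores(runA$predictions$val)
    po <- predScores(runD$predictions$val)
    grid <- seq(0, 1, by = 0.05)
    aucs <- vapply(grid, function(wi)
      tryCatch(rocAUC(lateFusion(pa, po, wi), labs),
               error = function(e) NA_real_), numeric(1))
    if (any(!is.na(aucs))) w <- grid[which.max(aucs)]
  }
  model <- list(type = "late", name = "LateFusion",
                amil = runA$model, dmlp = runD$model, w = w)
  preds <- lapply(list(train = trainIds(split), val = va,
                       test = testIds(split)),
                  function(ids) {
                    if (!length(ids)) return(NULL)
                    predictModel(model, cohort, ids, omicFeatures)
                  })
  structure(list(modelName = "LateFusion",
                 history = list(AMIL = runA$history, DMLP = runD$history),
                 bestEpoch = c(AMIL = runA$bestEpoch, DMLP = runD$bestEpoch),
                 model = model, predictions = preds, config = config,
                 components = list(AMIL = runA, DMLP = runD)),
            class = "TrainRun")
}

#' Five-fold patient-level cross-validation
#'
#' Seeded k folds over patients; each fold serves once as the test set
#' while the remaining patients are split 3:1 into train and validation
#' for checkpoint selection. Molecular features are refitted on each
#' fold's training patients only. If a plain random fold misses a class
#' the folds are redrawn with per-class stratification (logged via a
#' message). Reports per-fold AUC/precision/recall/F1 and their
#' mean +/- sample sd.
#'
#' @param cohort a [MultiModalCohort-class].
#' @param modelName one of [modelRegistry()].
#' @param config a [trainConfig()].
#' @param k number of folds (>= 2).
#' @param lfcThreshold,pThreshold DEG thresholds for the per-fold feature
#'   fit.
#' @return list with `perFold` (data.frame), `mean`, `sd`.
#' @export
crossValidate <- function(cohort, modelName, config = trainConfig(),
                          k = 5L, lfcThreshold = 2, pThreshold = 0.05) {
  stopifnot(k >= 2L)
  ids <- patientIds(cohort)
  labs <- cohortLabels(cohort)
  set.seed(config$seed)
  shuffled <- sample(ids)
  foldOf <- setNames(rep(seq_len(k), length.out = length(ids)), shuffled)[ids]
  bad <- any(vapply(seq_len(k), function(f)
    length(unique(labs[ids[foldOf == f]])) < 2L, logical(1)))
  if (bad) {
    message("a fold missed a class; redrawing folds with stratification")
    foldOf <- setNames(integer(length(ids)), ids)
    for (cl in unique(labs)) {
      clIds <- sample(ids[labs[ids] == cl])
      foldOf[clIds] <- rep(seq_len(k), length.out = length(clIds))
    }
  }
  perFold <- data.frame(fold = seq_len(k), auc = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_)
  for (f in seq_len(k)) {
    testF <- ids[foldOf == f]
    rest <- ids[foldOf != f]
    innerSeed <- config$seed + f
    set.seed(innerSeed)
    rest <- sample(rest)
    nTrain <- floor(0.75 * length(rest))
    asg <- setNames(c(rep("train", nTrain),
                      rep("val", length(rest) - nTrain)), rest)
    asg[testF] <- "test"
    split <- new("SplitAssignment",
                 assignment = factor(asg[ids],
                                     levels = c("train", "val", "test")),
                 ratio = c(0.6, 0.2, 0.2), seed = as.integer(innerSeed))
    omic <- if (modelName != "AMIL")
      suppressWarnings(fitOmicFeatures(cohort, trainIds(split),
                                       lfcThreshold, pThreshold))
    else NULL
    cfg <- config; cfg$seed <- innerSeed
    run <- trainModel(cohort, split, modelName, cfg, omic)
    ps <- run$predictions$test
    perFold$auc[f] <- rocAUC(ps)
    prf <- precisionRecallF1(predScores(ps), predLabels(ps))
    perFold$precision[f] <- prf[["precision"]]
    perFold$recall[f] <- prf[["recall"]]
    perFold$f1[f] <- prf[["f1"]]
  }
  metrics <- c("auc", "precision", "recall", "f1")
  list(perFold = perFold, foldOf = foldOf,
       mean = vapply(perFold[metrics], mean, numeric(1)),
       sd = vapply(perFold[metrics], sd, numeric(1)))
}

#' Leakage audit of fitted preprocessing state
#'
#' Asserts that every patient the molecular feature extractor (DEG
#' selection and z-score parameters) was fitted on belongs to the
#' training split; test or validation patients influencing fitted state is
#' an error.
#'
#' @param omicFeatures an `OmicFeatures` object.
#' @param split a [SplitAssignment-class].
#' @return `TRUE` invisibly on success; otherwise an error.
#' @export
noLeakageAudit <- function(omicFeatures, split) {
  stopifnot(inherits(omicFeatures, "OmicFeatures"),
            is(split, "SplitAssignment"))
  leaked <- setdiff(omicFeatures$fitPatients, trainIds(split))
  if (length(leaked))
    stop("leakage: preprocessing was fitted on non-training patients: ",
         paste(head(leaked, 5), collapse = ", "))
  invisible(TRUE)
}
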