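#' Pipeline configuration
#'
#' One configuration drives all pipeline stages: the synthetic cohort (or
#' a directory of on-disk inputs), the DEG screen thresholds, the training
#' protocol and the models to train. The shipped `"default"` profile
#' mirrors the fixed study protocol (6:2:2 split with seed 2024, 100
#' epochs); the `"fast"` profile (20 epochs, small cohort) keeps smoke
#' runs short.
#'
#' @param profile `"default"` or `"fast"`.
#' @param ... overrides for any top-level field.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(profile = c("default", "fast"), ...) {
  profile <- match.arg(profile)
  base <- list(
    cohort_dir = NULL,
    synthetic = unclass(syntheticSpec()),
    split_seed = 2024L,
    split_ratio = c(0.6, 0.2, 0.2),
    stratify = FALSE,
    lfc_threshold = 2,
    p_threshold = 0.05,
    de_method = "welch",
    models = c("AMIL", "DMLP", "LateFusion", "MMF_Kron", "MMF_Con",
               "ProMMF_Kron", "ProMMF_Con"),
    train = list(learningRate = 1e-4, weightDecay = 5e-3, epochs = 100L,
                 dropout = 0.1, seed = 1L),
    fusion = list(iterations = 2L, unimodalDim = 32L,
                  classifierHidden = 64L,
                  shareBackprojectionWeights = TRUE,
                  lateFusionWeight = 0.5),
    comparison = list(nBoot = 2000L, nPerm = 5000L, nSim = 2000L))
  if (profile == "fast") {
    base$synthetic <- unclass(syntheticSpec(nPatients = 60, nGenes = 300,
                                            nDeUp = 10, nDeDown = 10))
    base$train$epochs <- 20L
    base$stratify <- TRUE
    base$models <- c("AMIL", "DMLP", "ProMMF_Kron")
    base$comparison <- list(nBoot = 500L, nPerm = 1000L, nSim = 500L)
  }
  structure(modifyList(base, list(...)), class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  profile <- if (is.null(obj$profile)) "default" else obj$profile
  obj$profile <- NULL
  do.call(pipelineConfig, c(list(profile = profile), obj))
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.trainConfigOf <- function(config) {
  fus <- do.call(fusionConfig, config$fusion)
  do.call(trainConfig, c(config$train, list(fusion = fus)))
}

#' Run the full pipeline
#'
#' Generate (or load) the cohort, split patients 6:2:2, fit the molecular
#' features on the training split only (with a leakage audit), train every
#' requested model, evaluate test-set metrics, and compute all pairwise
#' model comparisons. One model failing is isolated: its error is recorded
#' in the manifest and the remaining models still run. Identical
#' configuration and seeds reproduce the run bit-identically (modulo
#' timestamps).
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory; when given, writes the config
#'   snapshot, split JSON, metrics CSV, per-model score CSVs, comparison
#'   reports and `manifest.json`.
#' @return the run manifest (list) invisibly when writing, else visibly.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  cohort <- if (!is.null(config$cohort_dir)) readCohort(config$cohort_dir)
            else generateCohort(do.call(syntheticSpec, config$synthetic))
  split <- patientLevelSplit(patientIds(cohort), config$split_ratio,
                             seed = config$split_seed,
                             stratify = config$stratify,
                             labels = cohortLabels(cohort))
  omic <- suppressWarnings(
    fitOmicFeatures(cohort, trainIds(split), config$lfc_threshold,
                    config$p_threshold, method = config$de_method))
  audit <- tryCatch({noLeakageAudit(omic, split); "pass"},
                    error = function(e) conditionMessage(e))

  runs <- list(); failures <- list()
  for (m in config$models) {
    res <- tryCatch(
      trainModel(cohort, split, m, .trainConfigOf(config), omic),
      error = function(e) e)
    if (inherits(res, "error")) failures[[m]] <- conditionMessage(res)
    else runs[[m]] <- res
  }

  metrics <- do.call(rbind, lapply(names(runs), function(m) {
    ps <- runs[[m]]$predictions$test
    prf <- precisionRecallF1(predScores(ps), predLabels(ps))
    data.frame(model = m, auc = rocAUC(ps),
               precision = prf[["precision"]], recall = prf[["recall"]],
               f1 = prf[["f1"]], stringsAsFactors = FALSE)
  }))

  comparisons <- list()
  nm <- names(runs)
  if (length(nm) >= 2L) {
    for (i in seq_len(length(nm) - 1L)) for (j in (i + 1L):length(nm)) {
      key <- paste(nm[i], "vs", nm[j])
      comparisons[[key]] <- compareModels(
        runs[[nm[i]]]$predictions$test, runs[[nm[j]]]$predictions$test,
        nBoot = config$comparison$nBoot, nPerm = config$comparison$nPerm,
        nSim = config$comparison$nSim, seed = config$train$seed)
    }
  }

  manifest <- list(
    config = unclass(config),
    seeds = list(split = config$split_seed, train = config$train$seed),
    split = lapply(split(names(split@assignment), split@assignment), identity),
    n_deg = list(up = nrow(omic$degs$up), down = nrow(omic$degs$down),
                 used_fallback = omic$usedFallback),
    leakage_audit = audit,
    metrics = metrics,
    comparisons = lapply(comparisons, function(r) list(
      auc_a = r@aucA, auc_b = r@aucB, ci_a = r@ciA, ci_b = r@ciB,
      delta = r@deltaObserved, p_permutation = r@pPermutation,
      cohen_d = r@cohenD, cohen_defined = r@cohenDefined,
      power = r@power)),
    failures = failures,
    package_version = as.character(packageVersion("kronmil")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePipelineConfig(config, file.path(outDir, "config.yaml"))
    jsonlite::write_json(manifest$split, file.path(outDir, "split.json"),
                         auto_unbox = FALSE)
    data.table::fwrite(metrics, file.path(outDir, "metrics.csv"))
    for (m in names(runs)) {
      ps <- runs[[m]]$predictions$test
      data.table::fwrite(
        data.frame(patient_id = patientIds(ps), score = predScores(ps),
                   label = predLabels(ps)),
        file.path(outDir, paste0("scores_", m, ".csv")))
      hist <- runs[[m]]$history
      if (is.data.frame(hist))
        data.table::fwrite(hist, file.path(outDir,
                                           paste0("history_", m, ".csv")))
    }
    for (key in names(comparisons))
      writeComparisonReport(comparisons[[key]],
        file.path(outDir, paste0("compare_", gsub(" ", "_", key), ".json")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    manifest$runs <- runs
    return(invisible(manifest))
  }
  manifest$runs <- runs
  manifest
}

#' Compare two score files
#'
#' CLI-facing wrapper: reads two CSVs with columns `patient_id`, `score`,
#' `label` and runs [compareModels()] on them.
#'
#' @param fileA,fileB score CSV paths.
#' @param nBoot,nPerm,nSim,seed passed to [compareModels()].
#' @return A [ComparisonReport-class].
#' @export
compareScoreFiles <- function(fileA, fileB, nBoot = 2000L, nPerm = 5000L,
                              nSim = 2000L, seed = 1L) {
  rd <- function(p) {
    df <- as.data.frame(data.table::fread(p))
    need <- c("patient_id", "score", "label")
    if (!all(need %in% names(df)))
      stop("score file must have columns ", paste(need, collapse = ", "))
    PredictionSet(df$patient_id, df$score, df$label)
  }
  compareModels(rd(fileA), rd(fileB), nBoot = nBoot, nPerm = nPerm,
                nSim = nSim, seed = seed)
}
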