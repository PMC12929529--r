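#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata
#' @importFrom stats rnorm runif rbinom rnbinom rpois rlnorm qnorm qt pt sd
#'   quantile median setNames
#' @importFrom utils head modifyList packageVersion
#' @importFrom Rcpp evalCpp
#' @useDynLib kronmil, .registration = TRUE
NULL

.EXPR_STAGES <- c("counts", "tpm", "log_tpm", "zscore")

#' Staged gene-by-patient expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one assay
#' (`"expr"`, genes as rows, patients as columns) plus a `stage` tag that
#' records where the matrix sits in the fixed preprocessing ladder
#' `counts -> tpm -> log_tpm -> zscore`. Stage transitions only ever move
#' forward along this ladder ([countsToTPM()], [logZNormalize()]).
#'
#' @slot stage character; one of `"counts"`, `"tpm"`, `"log_tpm"`, `"zscore"`.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(stage = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@stage) != 1L || !object@stage %in% .EXPR_STAGES)
    msg <- c(msg, sprintf("stage must be one of %s",
                          paste(.EXPR_STAGES, collapse = ", ")))
  v <- SummarizedExperiment::assay(object)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "gene and patient ids (dimnames) are required")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated gene ids")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated patient ids")
  if (any(!is.finite(v))) msg <- c(msg, "non-finite expression values")
  if (identical(object@stage, "counts") &&
      (any(v < 0) || any(v != round(v))))
    msg <- c(msg, "counts stage requires non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes as rows, patients as columns.
#' @param geneIds,patientIds character vectors; default to `dimnames(values)`.
#' @param stage preprocessing stage tag (see [ExpressionMatrix-class]).
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("P1", "P2")))
#' ExpressionMatrix(m, stage = "counts")
#' @export
ExpressionMatrix <- function(values, geneIds = rownames(values),
                             patientIds = colnames(values),
                             stage = c("counts", "tpm", "log_tpm", "zscore")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  dimnames(values) <- list(geneIds, patientIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values))
  new("ExpressionMatrix", se, stage = stage)
}

#' @rdname ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "expr")

#' @rdname ExpressionMatrix
#' @export
exprStage <- function(x) x@stage

#' Multimodal patient cohort
#'
#' The central data container: per-patient bags of 2048-d tile embeddings
#' paired with a raw gene-count matrix and binary MSI/MSS labels. The
#' patient is the unit of splitting and batching; every tile and the
#' expression profile of a patient travel together.
#'
#' @slot tileFeatures named list; one `M_i x 2048` numeric matrix per patient
#'   (`M_i >= 1` tiles).
#' @slot expr an [ExpressionMatrix-class] at stage `"counts"`.
#' @slot labels named integer vector, 1 = MSI (positive), 0 = MSS.
#' @slot geneLengths numeric vector of gene lengths in base pairs
#'   (length 0 when unknown).
#' @slot patientMeta data.frame of optional per-patient metadata
#'   (e.g. stage group, prior treatment), rownames = patient ids.
#' @slot spec list; the generating [syntheticSpec()] when synthetic,
#'   else empty.
#' @export
setClass("MultiModalCohort", representation(
  tileFeatures = "list",
  expr = "ExpressionMatrix",
  labels = "integer",
  geneLengths = "numeric",
  patientMeta = "data.frame",
  spec = "list"))

setValidity("MultiModalCohort", function(object) {
  msg <- character()
  ids <- names(object@tileFeatures)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "tileFeatures must be a uniquely named list")
  if (!identical(sort(ids), sort(colnames(exprValues(object@expr)))))
    msg <- c(msg, "tile bags and expression columns must cover the same patients")
  if (!identical(sort(ids), sort(names(object@labels))))
    msg <- c(msg, "labels must be named by the same patients")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 (MSS) or 1 (MSI)")
  for (id in ids) {
    x <- object@tileFeatures[[id]]
    if (!is.matrix(x) || nrow(x) < 1L) {
      msg <- c(msg, sprintf("bag for %s must be a matrix with >= 1 tile", id))
      break
    }
    if (any(!is.finite(x))) {
      msg <- c(msg, sprintf("non-finite tile features for %s", id))
      break
    }
  }
  nl <- length(object@geneLengths)
  if (nl && nl != nrow(exprValues(object@expr)))
    msg <- c(msg, "geneLengths must align with the gene dimension")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiModalCohort
#'
#' @param tileFeatures named list of `M_i x 2048` matrices (names = patient ids).
#' @param counts gene x patient count matrix or an [ExpressionMatrix-class]
#'   at stage `"counts"`.
#' @param labels named binary vector (1 = MSI).
#' @param geneLengths optional gene lengths (bp), aligned to the genes.
#' @param patientMeta optional data.frame of per-patient metadata.
#' @param spec optional generating spec (stored for provenance).
#' @return A [MultiModalCohort-class].
#' @export
MultiModalCohort <- function(tileFeatures, counts, labels,
                             geneLengths = numeric(0),
                             patientMeta = NULL, spec = list()) {
  if (!is(counts, "ExpressionMatrix"))
    counts <- ExpressionMatrix(counts, stage = "counts")
  ids <- names(tileFeatures)
  if (is.null(patientMeta))
    patientMeta <- data.frame(row.names = ids)
  new("MultiModalCohort",
      tileFeatures = tileFeatures, expr = counts,
      labels = setNames(as.integer(labels[ids]), ids),
      geneLengths = as.numeric(geneLengths),
      patientMeta = patientMeta,
      spec = if (is.list(spec)) spec else as.list(spec))
}

#' @rdname MultiModalCohort
#' @param object,x a `MultiModalCohort`.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname MultiModalCohort
#' @export
setMethod("patientIds", "MultiModalCohort",
          function(x) names(x@tileFeatures))

#' @rdname MultiModalCohort
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' @rdname MultiModalCohort
#' @export
setMethod("cohortLabels", "MultiModalCohort", function(x) x@labels)

#' @rdname MultiModalCohort
#' @param id a patient id.
#' @export
tileBag <- function(x, id) {
  stopifnot(is(x, "MultiModalCohort"))
  bag <- x@tileFeatures[[id]]
  if (is.null(bag)) stop("unknown patient id: ", id)
  bag
}

#' @rdname MultiModalCohort
#' @export
geneCounts <- function(x) exprValues(x@expr)

#' @rdname MultiModalCohort
#' @export
geneLengths <- function(x) x@geneLengths

#' @rdname MultiModalCohort
#' @export
setMethod("show", "MultiModalCohort", function(object) {
  M <- vapply(object@tileFeatures, nrow, 1L)
  cat(sprintf(paste0(
    "MultiModalCohort: %d patients (%d MSI / %d MSS)\n",
    "  tiles: %d total, bag sizes %d-%d, embedding dim %d\n",
    "  genes: %d%s\n"),
    length(M), sum(object@labels == 1L), sum(object@labels == 0L),
    sum(M), min(M), max(M), ncol(object@tileFeatures[[1L]]),
    nrow(exprValues(object@expr)),
    if (length(object@geneLengths)) " (lengths available)" else ""))
})

#' Patient-aligned prediction scores
#'
#' Holds one model's scores on a set of patients together with the true
#' labels; the common currency consumed by every metric and comparison
#' statistic. Scores are typically MSI probabilities but any monotone
#' decision value is accepted.
#'
#' @slot patientIds character.
#' @slot scores numeric, finite, aligned to `patientIds`.
#' @slot labels integer 0/1 (1 = MSI).
#' @slot groups character; optional subgroup labels (length 0 when absent).
#' @export
setClass("PredictionSet", representation(
  patientIds = "character", scores = "numeric",
  labels = "integer", groups = "character"))

setValidity("PredictionSet", function(object) {
  msg <- character()
  n <- length(object@patientIds)
  if (length(object@scores) != n || length(object@labels) != n)
    msg <- c(msg, "patientIds, scores and labels must align")
  if (length(object@groups) && length(object@groups) != n)
    msg <- c(msg, "groups must align with patients when present")
  if (any(!is.finite(object@scores))) msg <- c(msg, "non-finite scores")
  if (!all(object@labels %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' @rdname PredictionSet-class
#' @param patientIds,scores,labels,groups see slots.
#' @return A `PredictionSet`.
#' @export
PredictionSet <- function(patientIds, scores, labels, groups = character(0)) {
  new("PredictionSet", patientIds = as.character(patientIds),
      scores = as.numeric(scores), labels = as.integer(labels),
      groups = as.character(groups))
}

#' @rdname PredictionSet-class
#' @param x a `PredictionSet`.
#' @export
setMethod("patientIds", "PredictionSet", function(x) x@patientIds)

#' @rdname PredictionSet-class
#' @export
predScores <- function(x) x@scores

#' @rdname PredictionSet-class
#' @export
predLabels <- function(x) x@labels

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d patients (%d MSI), scores in [%.3f, %.3f]\n",
              length(object@scores), sum(object@labels == 1L),
              min(object@scores), max(object@scores)))
})

#' Two-model AUC comparison report
#'
#' Output of [compareModels()]: paired-bootstrap AUCs and percentile
#' confidence intervals, the paired permutation p-value, paired Cohen's d,
#' and parametric Monte-Carlo power, for one (model A, model B) pair.
#'
#' @slot aucA,aucB observed AUCs.
#' @slot ciA,ciB 95% percentile bootstrap intervals.
#' @slot deltaObserved observed paired statistic (mean score difference).
#' @slot ciDelta 95% percentile interval of the bootstrap AUC difference.
#' @slot pPermutation two-sided permutation p-value.
#' @slot cohenD paired Cohen's d (`NA` when undefined).
#' @slot cohenDefined logical; `FALSE` when the difference sd is 0.
#' @slot cohenSign sign of the mean difference when d is undefined.
#' @slot power Monte-Carlo power at alpha = 0.05.
#' @slot nBoot,nPerm,nSim replicate counts used.
#' @slot seed integer seed used.
#' @export
setClass("ComparisonReport", representation(
  aucA = "numeric", aucB = "numeric",
  ciA = "numeric", ciB = "numeric",
  deltaObserved = "numeric", ciDelta = "numeric",
  pPermutation = "numeric",
  cohenD = "numeric", cohenDefined = "logical", cohenSign = "numeric",
  power = "numeric",
  nBoot = "integer", nPerm = "integer", nSim = "integer",
  seed = "integer"))

setValidity("ComparisonReport", function(object) {
  msg <- character()
  for (ci in list(object@ciA, object@ciB))
    if (length(ci) != 2L || any(ci < 0) || any(ci > 1) || ci[1] > ci[2])
      msg <- c(msg, "AUC confidence bounds must be ordered within [0, 1]")
  if (object@pPermutation <= 0 || object@pPermutation > 1)
    msg <- c(msg, "p must lie in (0, 1]")
  if (object@power < 0 || object@power > 1)
    msg <- c(msg, "power must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ComparisonReport", function(object) {
  dtxt <- if (object@cohenDefined) sprintf("%.3f", object@cohenD)
          else sprintf("undefined (sign %+d)", as.integer(object@cohenSign))
  cat(sprintf(paste0(
    "ComparisonReport (paired, n_boot=%d, n_perm=%d)\n",
    "  AUC A: %.4f [%.4f, %.4f]\n  AUC B: %.4f [%.4f, %.4f]\n",
    "  mean paired score difference: %+.4f\n",
    "  permutation p (two-sided): %.4g\n",
    "  paired Cohen's d: %s\n  MC power at alpha=0.05: %.3f\n"),
    object@nBoot, object@nPerm,
    object@aucA, object@ciA[1], object@ciA[2],
    object@aucB, object@ciB[1], object@ciB[2],
    object@deltaObserved, object@pPermutation, dtxt, object@power))
})

#' Patient-level split assignment
#'
#' Maps every patient to one of train/val/test. Produced by
#' [patientLevelSplit()]; the patient (never the tile) is the unit, so all
#' modalities of a patient inherit the same fold.
#'
#' @slot assignment named factor with levels train/val/test.
#' @slot ratio numeric length-3 split ratio.
#' @slot seed integer seed used for the shuffle.
#' @export
setClass("SplitAssignment", representation(
  assignment = "factor", ratio = "numeric", seed = "integer"))

setValidity("SplitAssignment", function(object) {
  msg <- character()
  if (!identical(levels(object@assignment), c("train", "val", "test")))
    msg <- c(msg, "levels must be train, val, test")
  if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
    msg <- c(msg, "assignment must be uniquely named by patient id")
  if (length(msg)) msg else TRUE
})

#' @rdname SplitAssignment-class
#' @param x a `SplitAssignment`.
#' @export
trainIds <- function(x) names(x@assignment)[x@assignment == "train"]

#' @rdname SplitAssignment-class
#' @export
valIds <- function(x) names(x@assignment)[x@assignment == "val"]

#' @rdname SplitAssignment-class
#' @export
testIds <- function(x) names(x@assignment)[x@assignment == "test"]

#' @rdname SplitAssignment-class
#' @export
splitOf <- function(x, ids) as.character(x@assignment[ids])

setMethod("show", "SplitAssignment", function(object) {
  tab <- table(object@assignment)
  cat(sprintf("SplitAssignment: %d train / %d val / %d test (seed %d)\n",
              tab["train"], tab["val"], tab["test"], object@seed))
})
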