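#' Convert raw counts to TPM
#'
#' Transcripts per million: per patient,
#' `TPM_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6`,
#' so every patient column sums to 1e6. When gene lengths are unavailable
#' the length term drops out and the result is counts per million (CPM),
#' with a warning.
#'
#' @param counts an [ExpressionMatrix-class] at stage `"counts"` (or a raw
#'   gene x patient count matrix).
#' @param geneLengths gene lengths in base pairs aligned to the genes, or
#'   `NULL` for CPM.
#' @return An [ExpressionMatrix-class] at stage `"tpm"`.
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "P1"))
#' exprValues(countsToTPM(ExpressionMatrix(m, stage = "counts"),
#'                        geneLengths = c(1000, 2000)))
#' @export
countsToTPM <- function(counts, geneLengths = NULL) {
  if (!is(counts, "ExpressionMatrix"))
    counts <- ExpressionMatrix(counts, stage = "counts")
  stopifnot(exprStage(counts) == "counts")
  v <- exprValues(counts)
  if (is.null(geneLengths)) {
    warning("gene lengths unavailable; computing CPM instead of TPM")
    rate <- v
  } else {
    if (length(geneLengths) != nrow(v))
      stop("gene length vector does not match the gene dimension")
    if (any(geneLengths <= 0)) stop("gene lengths must be positive")
    rate <- v / geneLengths
  }
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero patient column(s): ",
         paste(colnames(v)[tot == 0], collapse = ", "),
         " (TPM undefined)")
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  ExpressionMatrix(tpm, stage = "tpm")
}

#' log2(TPM + 1) and per-gene z-score normalization
#'
#' Applies `log2(x + 1)` and then standardizes each gene with mean and
#' standard deviation estimated on `fitPatients` only (the training split,
#' to avoid leakage); all patients, held-out ones included, are transformed
#' with those fitted parameters. Genes with zero variance on the fit set
#' are set to 0 everywhere and flagged.
#'
#' @param tpm an [ExpressionMatrix-class] at stage `"tpm"`.
#' @param fitPatients patient ids the parameters are estimated on.
#' @return An [ExpressionMatrix-class] at stage `"zscore"`, with attributes
#'   `fitPatients`, `mu`, `sigma` and `flaggedGenes` (zero-variance genes).
#' @export
logZNormalize <- function(tpm, fitPatients) {
  stopifnot(is(tpm, "ExpressionMatrix"), exprStage(tpm) == "tpm")
  v <- exprValues(tpm)
  fitPatients <- as.character(fitPatients)
  if (length(fitPatients) == 0L || !any(fitPatients %in% colnames(v)))
    stop("fit subset is empty or disjoint from the matrix")
  if (!all(fitPatients %in% colnames(v)))
    stop("unknown fit patients: ",
         paste(setdiff(fitPatients, colnames(v)), collapse = ", "))
  lg <- log2(v + 1)
  fit <- lg[, fitPatients, drop = FALSE]
  mu <- rowMeans(fit)
  sigma <- sqrt(rowSums((fit - mu)^2) / max(1L, ncol(fit) - 1L))
  flagged <- rownames(v)[sigma == 0]
  z <- (lg - mu) / ifelse(sigma == 0, 1, sigma)
  z[sigma == 0, ] <- 0
  out <- ExpressionMatrix(z, stage = "zscore")
  attr(out, "fitPatients") <- fitPatients
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  attr(out, "flaggedGenes") <- flagged
  out
}

#' Per-gene differential-expression screen
#'
#' The pluggable screening statistic that defines the molecular feature
#' set: counts are scaled to the median library size, `logFC` is
#' `log2((mean_MSI + 1) / (mean_MSS + 1))` on the normalized counts
#' (pseudocount 1), and the p-value comes from a per-gene two-sample test
#' on `log2(normalized + 1)` -- Welch's t by default, Wilcoxon rank-sum as
#' an alternative. Genes with zero counts everywhere get `logFC = 0`,
#' `p = 1` by convention. Nominal p-values are reported deliberately (the
#' screen pairs them with a fold-change threshold rather than correcting
#' for multiplicity); an externally computed table (e.g. from a
#' shrinkage-based count model) can be swapped in via [readDEGTable()].
#'
#' @param counts an [ExpressionMatrix-class] at stage `"counts"`.
#' @param groups binary vector aligned to patients (1 = MSI).
#' @param method `"welch"` or `"wilcoxon"`.
#' @return data.frame with columns `gene_id`, `logFC`, `p_value`.
#' @export
differentialExpression <- function(counts, groups,
                                   method = c("welch", "wilcoxon")) {
  if (!is.character(method) || !all(method %in% c("welch", "wilcoxon")))
    stop("unknown method; available statistics: welch, wilcoxon")
  method <- match.arg(method)
  stopifnot(is(counts, "ExpressionMatrix"), exprStage(counts) == "counts")
  v <- exprValues(counts)
  groups <- as.integer(groups)
  stopifnot(length(groups) == ncol(v))
  if (sum(groups == 1L) == 0L || sum(groups == 0L) == 0L)
    stop("both groups must be non-empty")

  libs <- colSums(v)
  norm <- sweep(v, 2, median(libs) / libs, "*")
  m1 <- rowMeans(norm[, groups == 1L, drop = FALSE])
  m0 <- rowMeans(norm[, groups == 0L, drop = FALSE])
  logFC <- log2((m1 + 1) / (m0 + 1))

  lg <- log2(norm + 1)
  x1 <- lg[, groups == 1L, drop = FALSE]
  x0 <- lg[, groups == 0L, drop = FALSE]
  p <- if (method == "welch") .welchRows(x1, x0) else .wilcoxRows(x1, x0)

  p[!is.finite(p)] <- 1  # all-tied or zero-variance genes
  allZero <- rowSums(v) == 0
  logFC[allZero] <- 0
  p[allZero] <- 1
  data.frame(gene_id = rownames(v), logFC = logFC, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# vectorized Welch t-test across genes (rows)
.welchRows <- function(x1, x0) {
  n1 <- ncol(x1); n0 <- ncol(x0)
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  v1 <- rowSums((x1 - mu1)^2) / max(1L, n1 - 1L)
  v0 <- rowSums((x0 - mu0)^2) / max(1L, n0 - 1L)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (mu1 - mu0) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1)))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 1  # zero variance in both groups
  p
}

.wilcoxRows <- function(x1, x0) {
  vapply(seq_len(nrow(x1)), function(i) {
    suppressWarnings(stats::wilcox.test(x1[i, ], x0[i, ])$p.value)
  }, numeric(1))
}

#' Threshold-based DEG selection
#'
#' Applies the screen's strict thresholds: up-regulated means
#' `logFC > lfcThreshold` and `p < pThreshold`; down-regulated means
#' `logFC < -lfcThreshold` and `p < pThreshold`; everything else is `ns`.
#' A gene sitting exactly on a threshold is excluded. The union of the two
#' lists defines the molecular feature index used downstream.
#'
#' @param records data.frame from [differentialExpression()] (columns
#'   `gene_id`, `logFC`, `p_value`).
#' @param lfcThreshold log2 fold-change threshold (default 2).
#' @param pThreshold p-value threshold (default 0.05).
#' @return list with `up` and `down` (data.frames sorted by p then |logFC|
#'   descending) and `table` (all records plus a `direction` column).
#' @export
selectDEGs <- function(records, lfcThreshold = 2, pThreshold = 0.05) {
  stopifnot(lfcThreshold > 0, pThreshold > 0)
  if (nrow(records) == 0L) {
    empty <- records[0, , drop = FALSE]
    records$direction <- character(0)
    return(list(up = empty, down = empty, table = records))
  }
  direction <- rep("ns", nrow(records))
  direction[records$logFC > lfcThreshold & records$p_value < pThreshold] <- "up"
  direction[records$logFC < -lfcThreshold & records$p_value < pThreshold] <- "down"
  records$direction <- direction
  ord <- order(records$p_value, -abs(records$logFC))
  sorted <- records[ord, , drop = FALSE]
  up <- sorted[sorted$direction == "up", , drop = FALSE]
  down <- sorted[sorted$direction == "down", , drop = FALSE]
  if (nrow(up) + nrow(down) == 0L)
    warning("no genes pass the DEG thresholds; ",
            "downstream feature selection will fall back to top-k by p")
  list(up = up, down = down, table = records)
}

#' Fit the molecular feature extractor on the training split
#'
#' Runs the DE screen on training patients only, selects the DEG union
#' under the strict thresholds (falling back to the `fallbackK` smallest
#' p-values when the selection is empty), and returns the z-scored
#' feature matrix for *all* patients with normalization parameters fitted
#' on the training split. The returned object records the ids it was
#' fitted on, which [noLeakageAudit()] checks.
#'
#' @param cohort a [MultiModalCohort-class].
#' @param fitIds training-split patient ids.
#' @param lfcThreshold,pThreshold DEG thresholds (defaults 2 and 0.05).
#' @param fallbackK fallback feature count when no gene passes.
#' @param method DE statistic passed to [differentialExpression()].
#' @param degTable optional externally computed DE table (gene_id, logFC,
#'   p_value) overriding the built-in screen.
#' @return list of class `OmicFeatures`: `features` (selected genes x all
#'   patients, z-scores), `degs` (the [selectDEGs()] result), `geneIds`,
#'   `fitPatients`, `usedFallback`.
#' @export
fitOmicFeatures <- function(cohort, fitIds, lfcThreshold = 2,
                            pThreshold = 0.05, fallbackK = 64,
                            method = "welch", degTable = NULL) {
  stopifnot(is(cohort, "MultiModalCohort"))
  fitIds <- as.character(fitIds)
  stopifnot(all(fitIds %in% patientIds(cohort)))
  counts <- cohort@expr
  if (is.null(degTable)) {
    sub <- ExpressionMatrix(geneCounts(cohort)[, fitIds, drop = FALSE],
                            stage = "counts")
    degTable <- differentialExpression(sub, cohortLabels(cohort)[fitIds],
                                       method = method)
  }
  degs <- withCallingHandlers(
    selectDEGs(degTable, lfcThreshold, pThreshold),
    warning = function(w) invokeRestart("muffleWarning"))
  sel <- c(degs$up$gene_id, degs$down$gene_id)
  usedFallback <- FALSE
  if (length(sel) == 0L) {
    usedFallback <- TRUE
    ord <- order(degTable$p_value, -abs(degTable$logFC))
    sel <- degTable$gene_id[head(ord, fallbackK)]
    warning("empty DEG selection; falling back to top-", length(sel),
            " genes by p-value")
  }
  lens <- if (length(geneLengths(cohort))) geneLengths(cohort) else NULL
  tpm <- if (is.null(lens)) suppressWarnings(countsToTPM(counts, NULL))
         else countsToTPM(counts, lens)
  z <- logZNormalize(tpm, fitIds)
  feats <- exprValues(z)[sel, , drop = FALSE]
  structure(list(features = feats, degs = degs, geneIds = sel,
                 fitPatients = fitIds, usedFallback = usedFallback),
            class = "OmicFeatures")
}

#' @rdname fitOmicFeatures
#' @param x an `OmicFeatures` object.
#' @param id patient id.
#' @return `omicVector` returns the DEG-indexed z-score feature vector of
#'   one patient.
#' @export
omicVector <- function(x, id) {
  stopifnot(inherits(x, "OmicFeatures"))
  if (!id %in% colnames(x$features)) stop("unknown patient id: ", id)
  x$features[, id]
}

#' Count-matrix and DEG-table text I/O
#'
#' TSV/CSV round-trip for the standard on-disk formats: a count matrix with
#' genes as rows (first column `gene_id`, header row of patient ids) and a
#' DEG table with columns `gene_id`, `logFC`, `p_value` (and `direction`
#' when written by the package). `readDEGTable` also serves as the importer
#' for externally computed differential-expression results.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param path file path (`.tsv` or `.csv`; the separator follows the
#'   extension).
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
writeCountsMatrix <- function(expr, path) {
  stopifnot(is(expr, "ExpressionMatrix"))
  v <- exprValues(expr)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  data.table::fwrite(df, path, sep = if (grepl("\\.csv$", path)) "," else "\t")
  invisible(path)
}

#' @rdname writeCountsMatrix
#' @param stage stage tag for the matrix being read.
#' @export
readCountsMatrix <- function(path, stage = "counts") {
  df <- as.data.frame(data.table::fread(path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ExpressionMatrix(m, stage = stage)
}

#' @rdname writeCountsMatrix
#' @param degTable data.frame of DEG records.
#' @export
writeDEGTable <- function(degTable, path) {
  data.table::fwrite(degTable, path, sep = "\t")
  invisible(path)
}

#' @rdname writeCountsMatrix
#' @export
readDEGTable <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("gene_id", "logFC", "p_value")
  if (!all(need %in% names(df)))
    stop("DEG table must have columns ", paste(need, collapse = ", "))
  df
}
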