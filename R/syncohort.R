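#' Synthetic cohort specification
#'
#' Collects every knob of the synthetic multimodal generator. Defaults
#' describe the study conditions the package emulates: a gastric-cancer-like
#' cohort with ~22% MSI prevalence, negative-binomial RNA-seq counts with
#' planted differentially expressed genes at |log2 fold change| > 2, and
#' per-patient bags of 2048-d tile embeddings in which only a minority of
#' an MSI patient's tiles carry the class signal (the standard
#' multiple-instance assumption). Bag sizes are scaled down from
#' whole-slide practice so cohorts remain desk-sized.
#'
#' @param nPatients number of patients (>= 10).
#' @param prevalence MSI prevalence; default 0.22.
#' @param nGenes number of genes.
#' @param nDeUp,nDeDown planted up-/down-regulated gene counts in MSI.
#' @param deLogfc planted log2 fold-change magnitude (> 2 by default).
#' @param nbDispersion NB dispersion; variance = mu + mu^2 * dispersion.
#' @param geneLengthRange gene length range in base pairs.
#' @param bagSizeRange (min, max) tiles per patient, min >= 1.
#' @param informativeFraction probability that a tile of an MSI patient is
#'   informative (carries the embedding shift).
#' @param imageEffect mean-shift magnitude added to each signal coordinate
#'   of an informative tile.
#' @param signalDim number of informative embedding coordinates (<= embedDim).
#' @param modalityBalance fraction of the class signal allocated to the
#'   image modality: the image effect is scaled by `min(1, 2*b)` and the
#'   gene fold change by `min(1, 2*(1-b))`, so `b = 0.5` leaves both at
#'   their stated magnitudes, `b = 1` silences the genes and `b = 0`
#'   silences the images.
#' @param embedDim tile-embedding width (2048, the global-average-pooled
#'   convolutional backbone contract).
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return A validated list of class `SyntheticSpec`.
#' @examples
#' sp <- syntheticSpec(nPatients = 40, nGenes = 100, seed = 1)
#' generateCohort(sp)
#' @export
syntheticSpec <- function(nPatients = 200, prevalence = 0.22,
                          nGenes = 2000, nDeUp = 30, nDeDown = 30,
                          deLogfc = 2.5, nbDispersion = 0.3,
                          geneLengthRange = c(500, 5000),
                          bagSizeRange = c(5, 20),
                          informativeFraction = 0.3,
                          imageEffect = 1.0, signalDim = 32,
                          modalityBalance = 0.5,
                          embedDim = 2048L, seed = 1L) {
  spec <- list(nPatients = as.integer(nPatients), prevalence = prevalence,
               nGenes = as.integer(nGenes), nDeUp = as.integer(nDeUp),
               nDeDown = as.integer(nDeDown), deLogfc = deLogfc,
               nbDispersion = nbDispersion,
               geneLengthRange = as.numeric(geneLengthRange),
               bagSizeRange = as.integer(bagSizeRange),
               informativeFraction = informativeFraction,
               imageEffect = imageEffect, signalDim = as.integer(signalDim),
               modalityBalance = modalityBalance,
               embedDim = as.integer(embedDim), seed = as.integer(seed))
  with(spec, {
    stopifnot(nDeUp + nDeDown <= nGenes,
              prevalence >= 0, prevalence <= 1,
              informativeFraction >= 0, informativeFraction <= 1,
              modalityBalance >= 0, modalityBalance <= 1,
              bagSizeRange[1] >= 1, bagSizeRange[2] >= bagSizeRange[1],
              signalDim >= 1, signalDim <= embedDim,
              nbDispersion >= 0, deLogfc >= 0,
              all(geneLengthRange > 0))
  })
  structure(spec, class = "SyntheticSpec")
}

#' Generate a synthetic multimodal cohort
#'
#' Draws labels Bernoulli(prevalence); per-gene baseline means log-normal;
#' counts negative-binomial with the planted genes' means multiplied by
#' `2^(+/- deLogfc)` in MSI patients; per-patient tile bags of standard
#' Gaussian embeddings in which a Binomial(M_i, informativeFraction) subset
#' of each MSI patient's tiles is mean-shifted by `imageEffect` along
#' `signalDim` fixed coordinate directions. MSS bags are pure background
#' noise. Optional stage/treatment metadata is assigned independently of
#' the class. If a Bernoulli draw leaves one class empty the labels are
#' redrawn (still deterministic under the seed); a spec whose *expected*
#' minority count is below one is rejected outright.
#'
#' @param spec a [syntheticSpec()].
#' @return A [MultiModalCohort-class].
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$nPatients
  if (n < 10L)
    stop("refusing to generate a cohort with fewer than 10 patients")
  if (n * spec$prevalence < 1 || n * (1 - spec$prevalence) < 1)
    stop("spec leaves one class expected empty; unusable for training")
  set.seed(spec$seed)

  labels <- rbinom(n, 1L, spec$prevalence)
  tries <- 0L
  while ((sum(labels) == 0L || sum(labels) == n) && tries < 100L) {
    labels <- rbinom(n, 1L, spec$prevalence)
    tries <- tries + 1L
  }
  if (sum(labels) == 0L || sum(labels) == n)
    stop("could not draw both classes under this spec")

  ids <- sprintf("P%04d", seq_len(n))
  geneIds <- sprintf("G%05d", seq_len(spec$nGenes))

  mImg <- min(1, 2 * spec$modalityBalance)
  mGene <- min(1, 2 * (1 - spec$modalityBalance))

  baseMu <- rlnorm(spec$nGenes, meanlog = log(50), sdlog = 1.2)
  # plant DE genes on moderately expressed genes (baseline mean >= 20, or
  # the most expressed genes if too few qualify): fold changes on
  # near-zero counts are undetectable by any screen and unrealistic as
  # biomarker candidates
  nDe <- spec$nDeUp + spec$nDeDown
  eligible <- which(baseMu >= 20)
  if (length(eligible) < nDe)
    eligible <- order(baseMu, decreasing = TRUE)[seq_len(min(spec$nGenes, nDe))]
  deIdx <- if (length(eligible) == 1L) eligible
           else sample(eligible, nDe)
  upIdx <- deIdx[seq_len(spec$nDeUp)]
  downIdx <- deIdx[seq_len(spec$nDeDown) + spec$nDeUp]
  lfc <- spec$deLogfc * mGene
  muMSI <- baseMu
  muMSI[upIdx] <- muMSI[upIdx] * 2^lfc
  muMSI[downIdx] <- muMSI[downIdx] * 2^(-lfc)

  geneLen <- round(runif(spec$nGenes, spec$geneLengthRange[1],
                         spec$geneLengthRange[2]))

  drawCounts <- function(mu) {
    if (spec$nbDispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / spec$nbDispersion)
    else rpois(length(mu), mu)
  }
  counts <- matrix(0L, spec$nGenes, n, dimnames = list(geneIds, ids))
  for (j in seq_len(n))
    counts[, j] <- drawCounts(if (labels[j] == 1L) muMSI else baseMu)

  signalCoords <- sample.int(spec$embedDim, spec$signalDim)
  shift <- spec$imageEffect * mImg

  bags <- vector("list", n)
  names(bags) <- ids
  for (j in seq_len(n)) {
    M <- sample(spec$bagSizeRange[1]:spec$bagSizeRange[2], 1L)
    X <- matrix(rnorm(M * spec$embedDim), M, spec$embedDim)
    if (labels[j] == 1L) {
      k <- rbinom(1L, M, spec$informativeFraction)
      if (k > 0L) {
        rows <- sample.int(M, k)
        X[rows, signalCoords] <- X[rows, signalCoords] + shift
      }
    }
    bags[[j]] <- X
  }

  meta <- data.frame(
    stage_group = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
    prior_treatment = sample(c("none", "prior"), n, replace = TRUE),
    row.names = ids, stringsAsFactors = FALSE)

  cohort <- MultiModalCohort(
    tileFeatures = bags, counts = counts,
    labels = setNames(as.integer(labels), ids),
    geneLengths = geneLen, patientMeta = meta,
    spec = unclass(spec))
  cohort@spec$deUpGenes <- geneIds[upIdx]
  cohort@spec$deDownGenes <- geneIds[downIdx]
  cohort@spec$signalCoords <- signalCoords
  cohort
}

#' Paired score generator with known population AUCs
#'
#' Test harness for the AUC-comparison statistics: draws paired continuous
#' scores for two models from a binormal model in which the positive-class
#' mean of model k is `sqrt(2) * qnorm(auc_k)`, so the population AUC
#' equals the target exactly (`AUC = pnorm(mu / sqrt(2))` with unit
#' variances). The two models' noise terms share a common component with
#' correlation `pairingCorr`, making the construction exchangeable when the
#' two targets coincide -- the null of the paired permutation test then
#' holds by symmetry. A target AUC of exactly 1 is realised by shifting the
#' positive class deterministically past the negative-class maximum.
#'
#' @param n number of paired observations (>= 10).
#' @param aucA,aucB target AUCs in `[0.5, 1]`.
#' @param pairingCorr correlation of the two models' noise terms.
#' @param seed integer seed.
#' @return list with `scoresA`, `scoresB`, `labels` (half positives).
#' @export
generateScorePairs <- function(n, aucA, aucB, pairingCorr = 0.5, seed = 1L) {
  stopifnot(n >= 10, aucA >= 0.5, aucA <= 1, aucB >= 0.5, aucB <= 1,
            pairingCorr >= 0, pairingCorr <= 1)
  set.seed(as.integer(seed))
  n1 <- floor(n / 2)
  labels <- c(rep(0L, n - n1), rep(1L, n1))
  if (n1 == 0L || n1 == n) stop("degenerate n: a class would be empty")
  z0 <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n)
  ea <- sqrt(pairingCorr) * z0 + sqrt(1 - pairingCorr) * z1
  eb <- sqrt(pairingCorr) * z0 + sqrt(1 - pairingCorr) * z2
  mk <- function(auc, e) {
    if (auc >= 1) {
      gap <- max(e[labels == 0L]) - min(e[labels == 1L]) + 1
      e + labels * gap
    } else e + labels * (sqrt(2) * qnorm(auc))
  }
  list(scoresA = mk(aucA, ea), scoresB = mk(aucB, eb), labels = labels)
}

#' Write / read a cohort as plain-text files
#'
#' On-disk layout: `manifest.csv` (patient_id, label, n_tiles + metadata
#' columns), `counts.tsv` (first column gene_id, one column per patient),
#' `gene_lengths.tsv`, and one `tiles/<patient_id>.csv` matrix per patient
#' (the CSV tile-feature container; one file per patient plays the role of
#' one dataset per patient in a binary container).
#'
#' @param cohort a [MultiModalCohort-class].
#' @param dir output directory (created if missing).
#' @return `writeCohort` returns `dir` invisibly; `readCohort` returns the
#'   reconstructed [MultiModalCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "MultiModalCohort"))
  dir.create(file.path(dir, "tiles"), recursive = TRUE, showWarnings = FALSE)
  ids <- patientIds(cohort)
  man <- data.frame(patient_id = ids,
                    label = as.integer(cohortLabels(cohort)[ids]),
                    n_tiles = vapply(ids, function(i) nrow(tileBag(cohort, i)), 1L),
                    stringsAsFactors = FALSE)
  if (ncol(cohort@patientMeta))
    man <- cbind(man, cohort@patientMeta[ids, , drop = FALSE])
  data.table::fwrite(man, file.path(dir, "manifest.csv"))
  writeCountsMatrix(cohort@expr, file.path(dir, "counts.tsv"))
  if (length(geneLengths(cohort)))
    data.table::fwrite(
      data.frame(gene_id = rownames(geneCounts(cohort)),
                 length_bp = geneLengths(cohort)),
      file.path(dir, "gene_lengths.tsv"), sep = "\t")
  for (id in ids)
    data.table::fwrite(as.data.frame(tileBag(cohort, id)),
                       file.path(dir, "tiles", paste0(id, ".csv")))
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  man <- as.data.frame(data.table::fread(file.path(dir, "manifest.csv")))
  expr <- readCountsMatrix(file.path(dir, "counts.tsv"))
  lenFile <- file.path(dir, "gene_lengths.tsv")
  geneLen <- if (file.exists(lenFile)) {
    lt <- as.data.frame(data.table::fread(lenFile))
    lt$length_bp[match(rownames(exprValues(expr)), lt$gene_id)]
  } else numeric(0)
  ids <- as.character(man$patient_id)
  bags <- lapply(ids, function(id)
    as.matrix(data.table::fread(file.path(dir, "tiles", paste0(id, ".csv")))))
  names(bags) <- ids
  metaCols <- setdiff(names(man), c("patient_id", "label", "n_tiles"))
  meta <- man[metaCols]
  rownames(meta) <- ids
  MultiModalCohort(bags, expr, setNames(man$label, ids),
                   geneLengths = geneLen, patientMeta = meta)
}
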