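#' ROC AUC (Mann-Whitney form)
#'
#' Rank-based AUC: the probability that a random MSI patient scores above
#' a random MSS patient, with ties contributing 1/2.
#'
#' @param scores numeric scores (higher = more MSI-like), or a
#'   [PredictionSet-class].
#' @param labels binary labels (1 = MSI); ignored when `scores` is a
#'   `PredictionSet`.
#' @return AUC in `[0, 1]`.
#' @export
rocAUC <- function(scores, labels = NULL) {
  if (is(scores, "PredictionSet")) {
    labels <- predLabels(scores)
    scores <- predScores(scores)
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision, recall and F1 at a threshold
#'
#' MSI (label 1) is the positive class. Zero-denominator cases (no
#' predicted positives, no true positives, or precision + recall = 0)
#' return 0 for the affected metric, with a `"degenerate"` attribute
#' naming them.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param threshold classification threshold in (0, 1).
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
precisionRecallF1 <- function(scores, labels, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  degenerate <- character()
  precision <- if (tp + fp == 0L) { degenerate <- c(degenerate, "precision"); 0 }
               else tp / (tp + fp)
  recall <- if (tp + fn == 0L) { degenerate <- c(degenerate, "recall"); 0 }
            else tp / (tp + fn)
  f1 <- if (precision + recall == 0) { degenerate <- c(degenerate, "f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  structure(c(precision = precision, recall = recall, f1 = f1),
            degenerate = degenerate)
}

#' Per-subgroup metrics
#'
#' Computes the global metrics within each subgroup (e.g. pathologic
#' stage) exactly as they are computed globally. Subgroups missing a class
#' get `NA` AUC with a flag; empty groups are skipped.
#'
#' @param pred a [PredictionSet-class] carrying `groups`, or scores.
#' @param labels,groups used when `pred` is a plain score vector.
#' @param threshold threshold for precision/recall/F1.
#' @return data.frame with one row per group: `group`, `n`, `n_pos`,
#'   `auc`, `auc_defined`, `precision`, `recall`, `f1`.
#' @export
groupMetrics <- function(pred, labels = NULL, groups = NULL,
                         threshold = 0.5) {
  if (is(pred, "PredictionSet")) {
    labels <- predLabels(pred)
    if (is.null(groups)) groups <- pred@groups
    pred <- predScores(pred)
  }
  stopifnot(length(groups) == length(pred))
  out <- lapply(unique(groups), function(gr) {
    sel <- groups == gr
    if (!any(sel)) return(NULL)
    auc <- tryCatch(rocAUC(pred[sel], labels[sel]),
                    error = function(e) NA_real_)
    prf <- precisionRecallF1(pred[sel], labels[sel], threshold)
    data.frame(group = gr, n = sum(sel), n_pos = sum(labels[sel] == 1L),
               auc = auc, auc_defined = !is.na(auc),
               precision = prf[["precision"]], recall = prf[["recall"]],
               f1 = prf[["f1"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Paired bootstrap of two models' AUCs
#'
#' Resamples patient indices with replacement, applying the *same* index
#' vector to both models in every replicate (preserving pairing), and
#' computes both AUCs and their difference per replicate. 95% confidence
#' intervals use the percentile method (2.5th and 97.5th percentiles).
#' Replicates that lose one class are redrawn; the redraw count is
#' reported.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels binary labels.
#' @param nBoot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return list with `ciA`, `ciB`, `delta` (per-replicate AUC
#'   differences), `ciDelta`, `bootA`, `bootB`, `redraws`.
#' @export
pairedBootstrapAUC <- function(scoresA, scoresB, labels, nBoot = 2000L,
                               seed = 1L) {
  n <- length(labels)
  stopifnot(length(scoresA) == n, length(scoresB) == n)
  set.seed(as.integer(seed))
  bootA <- bootB <- numeric(nBoot)
  redraws <- 0L
  for (b in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      redraws <- redraws + 1L
      if (redraws > 10000L) stop("could not draw a two-class replicate")
    }
    bootA[b] <- rocAUC(scoresA[idx], labels[idx])
    bootB[b] <- rocAUC(scoresB[idx], labels[idx])
  }
  pct <- function(x) unname(quantile(x, c(0.025, 0.975), type = 7))
  list(ciA = pct(bootA), ciB = pct(bootB), delta = bootA - bootB,
       ciDelta = pct(bootA - bootB), bootA = bootA, bootB = bootB,
       redraws = redraws)
}

#' Paired permutation test for two models' scores
#'
#' Observed statistic `T = mean(scoresA - scoresB)`. Each permutation
#' independently swaps each patient's two model scores with probability
#' 0.5; the two-sided p-value is
#' `(1 + #(|T*| >= |T_obs|)) / (1 + nPerm)` (add-one smoothing, so p > 0).
#' The default mean-difference statistic follows the comparison protocol
#' literally; `statistic = "auc_difference"` recomputes the AUC difference
#' per permutation instead (requires `labels`), provided because comparing
#' AUCs through mean score differences is an unusual choice worth
#' cross-checking.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param nPerm permutation replicates (default 5000).
#' @param seed integer seed.
#' @param statistic `"mean_difference"` (default) or `"auc_difference"`.
#' @param labels binary labels, needed for the AUC statistic.
#' @return two-sided p-value in (0, 1].
#' @export
pairedPermutationTest <- function(scoresA, scoresB, nPerm = 5000L,
                                  seed = 1L,
                                  statistic = c("mean_difference",
                                                "auc_difference"),
                                  labels = NULL) {
  statistic <- match.arg(statistic)
  n <- length(scoresA)
  stopifnot(length(scoresB) == n)
  if (n < 2L) stop("need at least 2 pairs")
  set.seed(as.integer(seed))
  if (statistic == "mean_difference") {
    d <- scoresA - scoresB
    tObs <- mean(d)
    S <- matrix(sample(c(1, -1), nPerm * n, replace = TRUE), nPerm, n)
    tStar <- as.vector(S %*% d) / n
    (1 + sum(abs(tStar) >= abs(tObs) - 1e-15)) / (1 + nPerm)
  } else {
    if (is.null(labels)) stop("labels required for the AUC statistic")
    tObs <- rocAUC(scoresA, labels) - rocAUC(scoresB, labels)
    tStar <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
      swap <- runif(n) < 0.5
      a <- ifelse(swap, scoresB, scoresA)
      bb <- ifelse(swap, scoresA, scoresB)
      tStar[b] <- rocAUC(a, labels) - rocAUC(bb, labels)
    }
    (1 + sum(abs(tStar) >= abs(tObs) - 1e-15)) / (1 + nPerm)
  }
}

#' Paired Cohen's d
#'
#' `d = mean(diff) / sd(diff)` with the sample (n-1) standard deviation of
#' the per-patient score differences. A zero sd makes d undefined: the
#' result is then flagged (`defined = FALSE`) and only the sign of the
#' mean difference is reported.
#'
#' @param scoresA,scoresB paired score vectors (n >= 2).
#' @return list with `d`, `defined`, `sign`.
#' @examples
#' cohensDPaired(c(0.1, 0.2, 0.3), c(0, 0, 0))$d  # 2
#' @export
cohensDPaired <- function(scoresA, scoresB) {
  stopifnot(length(scoresA) == length(scoresB), length(scoresA) >= 2L)
  d <- scoresA - scoresB
  s <- sd(d)
  if (s == 0)
    list(d = NA_real_, defined = FALSE, sign = sign(mean(d)))
  else
    list(d = mean(d) / s, defined = TRUE, sign = sign(mean(d)))
}

#' Parametric Monte-Carlo power for a paired comparison
#'
#' Simulates `nSim` replicates of `n` paired differences from
#' `Normal(meanDiff, sdDiff^2)` and reports the fraction whose one-sample
#' t statistic exceeds the two-sided critical value at `alpha`. At zero
#' effect this recovers the test size (~alpha).
#'
#' @param meanDiff,sdDiff observed mean and sd of the paired differences
#'   (`sdDiff > 0`).
#' @param n number of pairs (>= 2).
#' @param alpha significance level.
#' @param nSim Monte-Carlo replicates.
#' @param seed integer seed.
#' @return power in `[0, 1]`.
#' @export
powerParametricMC <- function(meanDiff, sdDiff, n, alpha = 0.05,
                              nSim = 2000L, seed = 1L) {
  if (sdDiff <= 0) stop("sdDiff must be positive")
  stopifnot(n >= 2L)
  set.seed(as.integer(seed))
  sims <- matrix(rnorm(nSim * n, meanDiff, sdDiff), nSim, n)
  mu <- rowMeans(sims)
  s <- sqrt(rowSums((sims - mu)^2) / (n - 1))
  tstat <- mu / (s / sqrt(n))
  crit <- qt(1 - alpha / 2, n - 1)
  mean(abs(tstat) > crit)
}

#' Full two-model comparison
#'
#' Orchestrates the paired bootstrap, the paired permutation test, paired
#' Cohen's d and the parametric Monte-Carlo power (parameterized by the
#' observed mean and sd of the pairwise score differences) into one
#' [ComparisonReport-class]. Both prediction sets must cover the same
#' patients; `predB` is reordered to `predA`'s patients.
#'
#' @param predA,predB [PredictionSet-class]s on identical patients.
#' @param nBoot,nPerm,nSim replicate counts (defaults 2000 / 5000 / 2000).
#' @param seed integer seed for all three procedures.
#' @param statistic permutation statistic, see [pairedPermutationTest()].
#' @return A [ComparisonReport-class].
#' @export
compareModels <- function(predA, predB, nBoot = 2000L, nPerm = 5000L,
                          nSim = 2000L, seed = 1L,
                          statistic = "mean_difference") {
  stopifnot(is(predA, "PredictionSet"), is(predB, "PredictionSet"))
  if (!setequal(patientIds(predA), patientIds(predB)))
    stop("prediction sets cover different patients")
  ord <- match(patientIds(predA), patientIds(predB))
  sa <- predScores(predA)
  sb <- predScores(predB)[ord]
  la <- predLabels(predA)
  if (!identical(la, predLabels(predB)[ord]))
    stop("labels disagree between the two prediction sets")
  boot <- pairedBootstrapAUC(sa, sb, la, nBoot = nBoot, seed = seed)
  p <- pairedPermutationTest(sa, sb, nPerm = nPerm, seed = seed + 1L,
                             statistic = statistic, labels = la)
  cd <- cohensDPaired(sa, sb)
  diffs <- sa - sb
  pw <- if (sd(diffs) > 0)
    powerParametricMC(mean(diffs), sd(diffs), length(diffs),
                      nSim = nSim, seed = seed + 2L)
  else NA_real_
  new("ComparisonReport",
      aucA = rocAUC(sa, la), aucB = rocAUC(sb, la),
      ciA = boot$ciA, ciB = boot$ciB,
      deltaObserved = mean(diffs), ciDelta = boot$ciDelta,
      pPermutation = p,
      cohenD = cd$d, cohenDefined = cd$defined, cohenSign = cd$sign,
      power = if (is.na(pw)) 0 else pw,
      nBoot = as.integer(nBoot), nPerm = as.integer(nPerm),
      nSim = as.integer(nSim), seed = as.integer(seed))
}

#' Serialize a ComparisonReport to JSON
#'
#' @param report a [ComparisonReport-class].
#' @param path output path.
#' @export
writeComparisonReport <- function(report, path) {
  obj <- list(auc_a = report@aucA, auc_b = report@aucB,
              ci_a = report@ciA, ci_b = report@ciB,
              delta_observed = report@deltaObserved,
              ci_delta = report@ciDelta,
              p_permutation = report@pPermutation,
              cohen_d = report@cohenD,
              cohen_defined = report@cohenDefined,
              power = report@power,
              n_boot = report@nBoot, n_perm = report@nPerm,
              n_sim = report@nSim, seed = report@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
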