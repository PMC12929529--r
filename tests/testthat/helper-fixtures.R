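# Shared fixtures: everything is generated in code at test time.

# small, quick cohort for plumbing tests
smallCohort <- function(seed = 7, n = 40, strongImage = FALSE) {
  generateCohort(syntheticSpec(
    nPatients = n, nGenes = 200, nDeUp = 8, nDeDown = 8,
    bagSizeRange = c(3, 8),
    imageEffect = if (strongImage) 2.5 else 1.0,
    seed = seed))
}

# brute-force all-pairs AUC oracle (independent of the rank-based path)
aucBruteForce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# closed-form power of the two-sided one-sample t-test via the noncentral
# t distribution
powerClosedForm <- function(meanDiff, sdDiff, n, alpha = 0.05) {
  ncp <- meanDiff / (sdDiff / sqrt(n))
  crit <- qt(1 - alpha / 2, n - 1)
  pt(-crit, n - 1, ncp) + pt(crit, n - 1, ncp, lower.tail = FALSE)
}

# exhaustive paired-permutation p-value over all 2^n swap patterns
permExhaustive <- function(a, b) {
  n <- length(a)
  d <- a - b
  tObs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  tAll <- as.vector(signs %*% d) / n
  mean(abs(tAll) >= abs(tObs) - 1e-15)
}

# hand-set tiny gated-attention parameters (L = 2, projDim = 3) for
# scalar-traced oracles
tinyAttnParams <- function() {
  list(Va = matrix(c(0.3, -0.2, 0.1,
                     0.05, 0.4, -0.3), 2, 3, byrow = TRUE),
       Ua = matrix(c(-0.1, 0.2, 0.3,
                     0.25, -0.15, 0.05), 2, 3, byrow = TRUE),
       wa = c(0.7, -0.4))
}
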