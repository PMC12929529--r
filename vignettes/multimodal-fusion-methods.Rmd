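---
title: "Methods: gated-attention MIL, progressive Kronecker fusion, and paired AUC comparison"
author: "kronmil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gated-attention MIL, progressive Kronecker fusion, and paired AUC comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Microsatellite instability (MSI) marks tumors with defective DNA mismatch
repair; MSI patients respond far better to immune checkpoint inhibition
than microsatellite-stable (MSS) patients, so predicting MSI status from
routinely available data is clinically useful. In gastric adenocarcinoma
roughly 22% of patients are MSI. `kronmil` implements a multimodal
classifier that combines two such routine data sources per patient: a
*bag* of H&E tile embeddings from a whole-slide image, and a bulk
RNA-seq expression profile. The patient, not the tile, is the labelled
unit — the classic multiple-instance learning (MIL) setting, in which
only an unknown minority of a positive patient's tiles actually displays
the phenotype.

# Model

## Image branch: gated attention MIL

Each of a patient's \(M_i\) tiles arrives as a 2048-dimensional embedding
(the global-average-pooled output of a 50-layer residual network; the
backbone itself is a plugin, not part of the package). Each embedding is
mapped by a linear layer to \(h_m \in \mathbb{R}^{512}\), and a gated
attention head scores every instance:

\[
a_m = \operatorname{softmax}_m\!\big(w_a^\top
       (\tanh(V_a h_m) \odot \sigma(U_a h_m))\big),
\qquad
h_{\text{patient}} = \sum_m a_m h_m .
\]

The softmax runs over one patient's tiles only (bags never mix patients;
the batch size is 1 throughout), is computed with max-subtraction for
overflow safety, and yields weights on the simplex, so the pooled vector
is a convex combination of the instances — permutation-invariant and
contained in the instance hull coordinate-wise. The attention hidden
width is \(L = 256\) (a mid-sized default; the quantity is not pinned
down by the protocol and is exposed in `buildModel()`). One printed form
of the gate applies a transpose inside \(\sigma(U_a h_m^\top)\); shapes
are only consistent when both gate branches act on \(h_m\) as column
vectors, which is the standard gated-attention form and what the package
implements.

## Molecular branch: DEG screen and z-scored features

Raw counts are converted to TPM
(\(\mathrm{TPM}_g = (c_g/\ell_g)/\sum_h (c_h/\ell_h) \times 10^6\); CPM
with a warning when gene lengths are unavailable), transformed by
\(\log_2(x+1)\), and standardized per gene with mean and sd estimated on
the *training split only*. The feature set is the union of up- and
down-regulated genes from a per-gene screen on training patients:
\(|\log_2 \mathrm{FC}| > 2\) (strict) and \(p < 0.05\), with nominal
p-values by design — the screen selects candidate features for a
classifier, not a biological gene list, so multiplicity correction would
only shrink the candidate pool. The default statistic is a vectorized
Welch t-test on \(\log_2\)(median-library-normalized counts + 1), with a
Wilcoxon rank-sum option and an importer for externally computed tables
(e.g. from a shrinkage-based count model such as DESeq2); the reported
logFC is the raw \(\log_2\) ratio of normalized group means with
pseudocount 1, not a shrunken estimate. When nothing passes the screen,
a configurable top-\(k\)-by-p fallback keeps the pipeline runnable and is
flagged.

## Fusion

Both branches are reduced to 32-dimensional non-negative vectors
(linear + ReLU; the omic branch first passes a 128-unit MLP). The
intermediate fusion operator is either:

* **Kronecker** — append 1 to each vector and take the outer product
  \([h;1] \otimes [g;1]^\top\), flattened row-major to 1089 values. The
  augmentation guarantees that the fused matrix carries \((h,1)\) in its
  last column and \((g,1)\) in its last row, so each unimodal vector
  survives fusion verbatim while every other entry is a pairwise
  cross-modal product; or
* **concatenation** — the 64-vector \([h; g]\), image block first.

**Progressive refinement (the back-projection loop).** Starting from
\(f^{(0)} = \mathrm{fuse}(h, g)\), each of \(T\) cycles back-projects the
fused vector into the two unimodal spaces through learned affine maps,
adds the resulting context vectors to the *original* unimodal features
(unscaled addition), and re-fuses:

\[
(\hat h, \hat g) = B(f^{(t-1)}), \qquad
f^{(t)} = \mathrm{fuse}(h + \hat h,\; g + \hat g).
\]

\(T\) counts refinement cycles after the initial fusion and is
restricted to 1–5, with 2 the adopted default (the value selected by the
protocol's own hyperparameter search). With all back-projection
parameters at zero the model reduces *exactly* to single-pass fusion for
every \(T\) — the progressive model strictly contains the plain one — and
the test suite asserts this identity. The back-projection weights are
shared across cycles by default (the refinement reads most naturally as
a recurrent map); per-cycle weights are available behind
`shareBackprojectionWeights = FALSE` since the protocol does not say
which was used.

A one-hidden-layer head (64 units, ReLU, dropout 0.1) with a sigmoid
output converts the fused vector into an MSI probability. The head
architecture is not specified by the protocol; this is the smallest head
consistent with the model's overall parameter scale.

## Baselines

`AMIL` (image-only head on \(h_{\text{patient}}\)), `DMLP`
(gene-expression MLP, hidden sizes 128 then 32 mirroring the fusion
bottleneck), `LateFusion`
(\(w\,p_{\text{image}} + (1-w)\,p_{\text{omic}}\) with \(w = 0.5\) by
default, optionally tuned on the validation split by AUC grid search —
the protocol states weighted fusion without giving \(w\)), and the
single-pass `MMF_Kron` / `MMF_Con`.

# Training protocol

Patients are split 6:2:2 by floor/floor/remainder after a seeded shuffle
(282 patients give 169/56/57; the default shuffle seed is 2024),
unstratified by default to mirror the plain random protocol, with a
stratified switch for small synthetic cohorts. Optimization is Adam
(learning rate \(10^{-4}\), weight decay \(5\times 10^{-3}\)), binary
cross entropy, 100 epochs by default, batch size fixed to 1 because bags
differ in size — each step draws one patient's image and molecular
features together. Dropout 0.1 is applied to the projected instances,
the omic hidden layer and the classifier hidden layer; attention-branch
dropout is deliberately omitted (placement inside the gate is not pinned
down by the protocol). The checkpoint with the best validation AUC is
kept (the protocol is silent on selection; a validation split exists, so
it is used; ties resolve to the earlier epoch). Early stopping is off.
Five-fold cross-validation refits the molecular features inside every
fold and reports mean ± sample sd of AUC/precision/recall/F1.

All randomness — initialization, epoch shuffles, dropout, tile
subsampling — derives from the configured seed, and the gradients of
every head are hand-derived and checked against central finite
differences in the test suite, so two runs with one configuration agree
bit for bit.

## Numerical choices

Softmax and sigmoid are computed with max-subtraction and input clamping
at ±30; BCE clamps probabilities at \(10^{-12}\). Dropout is inverted
(scaling at train time), so evaluation mode is a pure deterministic
forward pass. Weights initialize Glorot-uniform, biases at zero. The
Adam update is a fused in-place C++ kernel whose first/second moments are
stored in single precision — the update is memory-bandwidth-bound and
moment quantization noise is orders of magnitude below gradient noise;
parameters themselves stay double. Zero-variance genes z-score to 0 and
are flagged; all-zero genes get logFC 0 and p 1; a degenerate
precision/recall denominator yields 0 with a flag rather than NaN.

# Paired comparison statistics

Two models are compared on the same test patients:

* **Paired bootstrap** (2000 replicates): one index vector per replicate
  is applied to *both* models; 95% CIs are percentile (2.5th/97.5th).
  Single-class replicates are redrawn and counted.
* **Paired permutation test** (5000 replicates): each patient's two
  scores swap independently with probability 0.5; the statistic is the
  mean paired score difference, read literally from the protocol, and
  the two-sided p-value uses add-one smoothing so \(p > 0\). Comparing
  AUCs through mean score differences is unusual, so an alternative
  statistic that recomputes the AUC difference per permutation is
  provided behind `statistic = "auc_difference"` rather than silently
  substituted.
* **Paired Cohen's d**: mean difference over its sample sd; a zero sd is
  flagged undefined (sign reported) instead of returning a number.
* **Parametric Monte-Carlo power**: simulate \(n\) paired differences
  from \(\mathcal N(\bar d, s_d^2)\) and count two-sided one-sample
  t-rejections at \(\alpha = 0.05\) (the protocol names only "the
  critical value"; the two-sided t is the matching concrete choice). At
  zero effect this recovers the size \(\approx \alpha\), which the tests
  assert, along with agreement with the noncentral-t closed form.

The default classification threshold for precision/recall/F1 is 0.5
(the protocol is silent), with subgroup metrics computed per group
exactly as globally and flagged when a subgroup lacks a class.

# The synthetic cohort generator

No real pathology or expression data ships with the package; every claim
is exercised on synthetic cohorts whose structure matches what the model
assumes:

* labels Bernoulli with 22% MSI prevalence;
* negative-binomial counts (variance \(\mu + \phi\mu^2\), \(\phi = 0.3\),
  the mean–dispersion convention of RNA-seq count models) with log-normal
  baseline means, and `nDeUp`/`nDeDown` planted genes whose MSI means are
  multiplied by \(2^{\pm \text{deLogfc}}\) (default magnitude 2.5, above
  the screen's threshold). DE genes are planted on moderately expressed
  genes (baseline mean ≥ 20): a fold change on a near-zero-count gene is
  undetectable by any screen and would not be a plausible biomarker;
* per-patient bags of standard-Gaussian 2048-d embeddings; in MSI
  patients a Binomial(\(M_i\), 0.3) subset of tiles is shifted by
  `imageEffect` (default 1.0) along 32 fixed coordinate directions — the
  MIL assumption that only some tiles reveal the label. MSS bags are pure
  noise, and some MSI bags may carry no informative tile, a realistic
  source of image-side label noise;
* `modalityBalance` allocates the class signal between modalities with
  clamped linear multipliers \(\min(1, 2b)\) on the image effect and
  \(\min(1, 2(1-b))\) on the gene fold change: \(b=1\) silences the genes,
  \(b=0\) silences the images, and \(b=0.5\) leaves both at their stated
  magnitudes (so a spec's nominal `deLogfc` is what a balanced cohort
  actually plants);
* optional stage/treatment metadata assigned independently of class, as
  plumbing for subgroup metrics without asserting biology.

Identical spec + seed reproduces a cohort bit-identically. What the
generator does **not** emulate: tile spatial context and morphology,
staining variation, batch effects, gene–gene correlation structure, and
DE signatures entangled with image signal. Tests passing on these
cohorts therefore demonstrate that the machinery — screening, pooling,
fusion, refinement, statistics — behaves as specified, not that the
model reaches any particular accuracy on real tumors.

# Problem sizes used by the tests

Bag sizes default to 5–20 tiles per patient; real whole-slide bags run
into the hundreds, and the scaled-down bags keep cohorts desk-sized
while preserving the variable-size, minority-informative structure that
MIL pooling must handle. The synthetic-recovery check trains on
300-patient cohorts for 20 epochs across 5 seeds, with the class signal
split evenly across modalities, and asserts the directional property
that progressive Kronecker fusion is at least as good (mean test AUC,
small tolerance) as each unimodal baseline, plus AUC ≥ 0.9 under strong
effects (`imageEffect = 2.5`, `deLogfc = 4`, informative fraction 0.5).
The statistics suite checks calibration at protocol-realistic sizes
(57 pairs) with replicate counts reduced to keep the suite quick; the
acceptance script runs a 200-patient, 20-epoch end-to-end study.

# Known limitations

* The DE screen is a two-sample location test, not a count-model fit; on
  real data its candidate list will differ from DESeq2's, and the logFC
  is unshrunk (noisy for low-count genes).
* With balanced strong effects the expression modality alone can already
  be nearly separable on synthetic data, so the multimodal margin over
  `DMLP` is often small there; the margin over the image-only model is
  the more informative one under the MIL noise model.
* The backbone contract is fixed at 2048-d embeddings; other backbones
  require re-projection outside the package.
* `LateFusion` trains its two components independently; no joint
  fine-tuning.
* Checkpoints serialize parameters as JSON text — portable and
  diff-able, but large for the image branch (~10 MB); keep them out of
  version control.
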