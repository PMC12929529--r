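#' Fusion configuration
#'
#' Architecture switches for the intermediate-fusion heads: the fusion
#' operator (`kron` = unit-augmented Kronecker product, `concat` = plain
#' concatenation), whether the progressive back-projection refinement is
#' active and for how many cycles `T` (searched over 1..5; 2 is the
#' adopted default), the 32-d unimodal bottleneck, dropout rate, the
#' classifier hidden width, whether back-projection weights are shared
#' across cycles, and the late-fusion mixing weight.
#'
#' @param mode `"kron"` or `"concat"`.
#' @param progressive logical; `FALSE` reduces to single-pass fusion.
#' @param iterations back-projection refinement cycles `T` in 1..5.
#' @param unimodalDim unimodal feature width (32).
#' @param dropout dropout probability in `[0, 1)`.
#' @param classifierHidden classifier hidden width.
#' @param shareBackprojectionWeights share one pair of back-projection
#'   maps across cycles (default) or learn one pair per cycle.
#' @param lateFusionWeight weight `w` on the image probability in
#'   [lateFusion()].
#' @param tuneLateWeight tune `w` on the validation split by AUC grid
#'   search instead of using the fixed default.
#' @return validated list of class `FusionConfig`.
#' @export
fusionConfig <- function(mode = c("kron", "concat"), progressive = TRUE,
                         iterations = 2L, unimodalDim = 32L,
                         dropout = 0.1, classifierHidden = 64L,
                         shareBackprojectionWeights = TRUE,
                         lateFusionWeight = 0.5, tuneLateWeight = FALSE) {
  mode <- match.arg(mode)
  iterations <- as.integer(iterations)
  if (iterations < 1L || iterations > 5L)
    stop("iterations must lie in 1..5")
  stopifnot(dropout >= 0, dropout < 1,
            lateFusionWeight >= 0, lateFusionWeight <= 1,
            unimodalDim >= 1, classifierHidden >= 1)
  structure(list(mode = mode, progressive = isTRUE(progressive),
                 iterations = iterations,
                 unimodalDim = as.integer(unimodalDim),
                 dropout = dropout,
                 classifierHidden = as.integer(classifierHidden),
                 shareBackprojectionWeights = isTRUE(shareBackprojectionWeights),
                 lateFusionWeight = lateFusionWeight,
                 tuneLateWeight = isTRUE(tuneLateWeight)),
            class = "FusionConfig")
}

#' Unit-augmented Kronecker fusion
#'
#' Appends 1 to each unimodal vector and takes the outer product
#' `[h_histology; 1] (x) [h_omic; 1]^T`, flattened row-major to a vector of
#' length `(d+1)^2` (1089 for the default d = 32). The augmentation makes
#' the fused matrix carry `(h_histology, 1)` in its last column and
#' `(h_omic, 1)` in its last row, so each unimodal vector survives fusion
#' intact while the remaining entries capture all pairwise cross-modal
#' interactions.
#'
#' @param hHistology,hOmic unimodal feature vectors of equal length `d`.
#' @return numeric vector of length `(d+1)^2`.
#' @examples
#' kronFuse(c(1, 2), c(3, 4))  # [3 4 1 6 8 2 3 4 1]
#' @export
kronFuse <- function(hHistology, hOmic) {
  stopifnot(length(hHistology) == length(hOmic),
            all(is.finite(hHistology)), all(is.finite(hOmic)))
  a <- c(hHistology, 1)
  b <- c(hOmic, 1)
  # column-major vector of outer(b, a) equals the row-major flattening of
  # the (histology x omic) fused matrix
  as.vector(outer(b, a))
}

#' @rdname kronFuse
#' @param f a fused vector from `kronFuse`.
#' @return `kronAsMatrix` returns the `(d+1) x (d+1)` fused matrix
#'   (histology index as rows).
#' @export
kronAsMatrix <- function(f) {
  d1 <- as.integer(sqrt(length(f)))
  stopifnot(d1 * d1 == length(f))
  matrix(f, d1, d1, byrow = TRUE)
}

#' Concatenation fusion
#'
#' Plain concatenation, image block first: a `2d` vector.
#'
#' @inheritParams kronFuse
#' @export
concatFuse <- function(hHistology, hOmic) {
  stopifnot(length(hHistology) == length(hOmic))
  c(hHistology, hOmic)
}

.fuse <- function(h, g, mode)
  if (mode == "kron") kronFuse(h, g) else concatFuse(h, g)

.fusedDim <- function(d, mode) if (mode == "kron") (d + 1L)^2 else 2L * d

# gradient of the fused vector w.r.t. the two unimodal inputs
.fuseBackward <- function(df, h, g, mode) {
  d <- length(h)
  if (mode == "kron") {
    G <- matrix(df, d + 1L, d + 1L)      # G[j, i]: omic row, histology col
    a <- c(h, 1); b <- c(g, 1)
    da <- as.vector(crossprod(G, b))
    db <- as.vector(G %*% a)
    list(dh = da[seq_len(d)], dg = db[seq_len(d)])
  } else {
    list(dh = df[seq_len(d)], dg = df[d + seq_len(d)])
  }
}

#' Back-projection parameter initialization
#'
#' One pair of affine maps from the fused space back to the two 32-d
#' unimodal spaces (`zeroInit = TRUE` starts them at zero, which makes the
#' progressive model coincide with single-pass fusion until training moves
#' the weights).
#'
#' @param fusedDim fused-vector length (1089 for kron, 64 for concat).
#' @param unimodalDim unimodal width (32).
#' @param zeroInit start at zero instead of Glorot-random.
#' @return list with `Bh`, `bbh`, `Bo`, `bbo`.
#' @export
backProjectionParams <- function(fusedDim, unimodalDim = 32L,
                                 zeroInit = FALSE) {
  if (zeroInit)
    list(Bh = matrix(0, unimodalDim, fusedDim), bbh = numeric(unimodalDim),
         Bo = matrix(0, unimodalDim, fusedDim), bbo = numeric(unimodalDim))
  else
    list(Bh = .glorot(unimodalDim, fusedDim), bbh = numeric(unimodalDim),
         Bo = .glorot(unimodalDim, fusedDim), bbo = numeric(unimodalDim))
}

#' Back-project a fused vector to the unimodal spaces
#'
#' Two affine maps with learnable parameter matrices produce the reverse
#' projection vectors `hhat_histology` and `hhat_omic` that feed the
#' progressive refinement.
#'
#' @param f fused vector.
#' @param params [backProjectionParams()].
#' @return list with `hhatHistology` and `hhatOmic`.
#' @export
backProject <- function(f, params) {
  stopifnot(ncol(params$Bh) == length(f), ncol(params$Bo) == length(f))
  list(hhatHistology = as.vector(params$Bh %*% f) + params$bbh,
       hhatOmic = as.vector(params$Bo %*% f) + params$bbo)
}

#' Progressive (back-projection) fusion
#'
#' Starting from `f0 = fuse(h, g)`, each of `T` refinement cycles
#' back-projects the current fused vector into the two unimodal spaces,
#' adds the resulting context vectors to the *original* unimodal features
#' (unscaled addition), and re-fuses:
#' `(hhat, ghat) = backProject(f[t-1]); f[t] = fuse(h + hhat, g + ghat)`.
#' With all back-projection parameters at zero the output equals `f0` for
#' every `T`, i.e. the progressive model contains single-pass fusion as a
#' special case. With `progressive = FALSE` the function returns `f0`.
#'
#' @param hHistology,hOmic unimodal feature vectors (length `d`).
#' @param config a [fusionConfig()].
#' @param params back-projection parameters: one
#'   [backProjectionParams()] list (shared across cycles) or a list of
#'   `iterations` of them (per-cycle weights).
#' @return the final fused vector `f[T]`.
#' @export
progressiveFuse <- function(hHistology, hOmic, config, params) {
  stopifnot(inherits(config, "FusionConfig"))
  out <- .progressiveCore(hHistology, hOmic, config$mode,
                          progressive = config$progressive,
                          iters = config$iterations,
                          backParams = .asBackList(params, config),
                          shared = config$shareBackprojectionWeights)
  out$f
}

.asBackList <- function(params, config) {
  if (!is.null(params$Bh)) list(params)
  else {
    if (!config$shareBackprojectionWeights &&
        length(params) != config$iterations)
      stop("per-cycle weights require one parameter set per iteration")
    params
  }
}

# forward core; keeps intermediates when cache = TRUE for backprop
.progressiveCore <- function(h, g, mode, progressive, iters, backParams,
                             shared, cache = FALSE) {
  f <- .fuse(h, g, mode)
  us <- vs <- fs <- NULL
  if (progressive) {
    if (iters < 1L || iters > 5L) stop("iterations must lie in 1..5")
    if (cache) { us <- vector("list", iters); vs <- us; fs <- vector("list", iters + 1L) }
    if (cache) fs[[1L]] <- f
    for (t in seq_len(iters)) {
      P <- backParams[[if (shared) 1L else t]]
      bp <- backProject(f, P)
      u <- h + bp$hhatHistology
      v <- g + bp$hhatOmic
      f <- .fuse(u, v, mode)
      if (cache) { us[[t]] <- u; vs[[t]] <- v; fs[[t + 1L]] <- f }
    }
  }
  list(f = f, us = us, vs = vs, fs = fs)
}

# backward through the refinement recurrence; returns dh, dg and grads for
# each back-projection slot (accumulated when shared)
.progressiveBackward <- function(df, h, g, mode, progressive, iters,
                                 backParams, shared, core) {
  nSlots <- if (!progressive) 0L else if (shared) 1L else iters
  dB <- lapply(seq_len(nSlots), function(i)
    list(Bh = backParams[[i]]$Bh * 0, bbh = backParams[[i]]$bbh * 0,
         Bo = backParams[[i]]$Bo * 0, bbo = backParams[[i]]$bbo * 0))
  dh <- h * 0; dg <- g * 0
  if (progressive) {
    for (t in rev(seq_len(iters))) {
      P <- backParams[[if (shared) 1L else t]]
      s <- if (shared) 1L else t
      bw <- .fuseBackward(df, core$us[[t]], core$vs[[t]], mode)
      dh <- dh + bw$dh
      dg <- dg + bw$dg
      fPrev <- core$fs[[t]]
      dB[[s]]$Bh <- dB[[s]]$Bh + outer(bw$dh, fPrev)
      dB[[s]]$bbh <- dB[[s]]$bbh + bw$dh
      dB[[s]]$Bo <- dB[[s]]$Bo + outer(bw$dg, fPrev)
      dB[[s]]$bbo <- dB[[s]]$bbo + bw$dg
      df <- as.vector(crossprod(P$Bh, bw$dh)) +
            as.vector(crossprod(P$Bo, bw$dg))
    }
  }
  bw0 <- .fuseBackward(df, h, g, mode)
  list(dh = dh + bw0$dh, dg = dg + bw0$dg, dB = dB)
}

#' Late fusion of unimodal probabilities
#'
#' Decision-level fusion: `w * p_image + (1 - w) * p_omic`.
#'
#' @param pImage,pOmic unimodal MSI probabilities in `[0, 1]`.
#' @param w image weight in `[0, 1]`.
#' @return fused probability.
#' @examples
#' lateFusion(0.2, 0.9, w = 0.3)  # 0.69
#' @export
lateFusion <- function(pImage, pOmic, w = 0.5) {
  if (any(w < 0) || any(w > 1)) stop("w must lie in [0, 1]")
  stopifnot(all(pImage >= 0 & pImage <= 1), all(pOmic >= 0 & pOmic <= 1))
  w * pImage + (1 - w) * pOmic
}

#' Unimodal bottleneck heads
#'
#' Maps the pooled 512-d image vector through a linear layer + ReLU to the
#' 32-d `h_histology`, and the DEG-indexed z-score vector through an MLP
#' (hidden 128, ReLU) followed by a linear layer + ReLU to the 32-d
#' `h_omic`. Both outputs are non-negative by construction.
#'
#' @param hPatient pooled image vector (length 512).
#' @param omicVec DEG-indexed molecular feature vector.
#' @param params list with `Wih`, `bih` (image head) and `Wo1`, `bo1`,
#'   `Wo2`, `bo2` (omic MLP); see [buildModel()].
#' @return list with `hHistology` and `hOmic` (length `unimodalDim`).
#' @export
unimodalHeads <- function(hPatient, omicVec, params) {
  if (ncol(params$Wo1) != length(omicVec))
    stop("omic feature vector does not match the selected DEG index (",
         ncol(params$Wo1), " expected, got ", length(omicVec), ")")
  h <- pmax(as.vector(params$Wih %*% hPatient) + params$bih, 0)
  r1 <- pmax(as.vector(params$Wo1 %*% omicVec) + params$bo1, 0)
  g <- pmax(as.vector(params$Wo2 %*% r1) + params$bo2, 0)
  list(hHistology = h, hOmic = g)
}

#' Classifier head over a fused vector
#'
#' One hidden layer (ReLU, dropout in training mode) and a sigmoid output:
#' the MSI probability. With all-zero parameters the output is exactly 0.5.
#'
#' @param f fused vector.
#' @param params list with `Wc`, `bc`, `wc`, `bc2`.
#' @param dropout dropout rate applied to the hidden layer when
#'   `train = TRUE`.
#' @param train training mode flag; evaluation mode is deterministic.
#' @return probability in (0, 1).
#' @export
classifyFused <- function(f, params, dropout = 0.1, train = FALSE) {
  z <- as.vector(params$Wc %*% f) + params$bc
  r <- pmax(z, 0) * .dropoutMask(length(z), dropout, train)
  .sigmoid(sum(params$wc * r) + params$bc2)
}

#' DMLP forward pass
#'
#' The unimodal gene-expression baseline: a multilayer perceptron
#' (hidden sizes 128 then 32, ReLU, dropout in training mode) over the
#' DEG-indexed z-score vector, with a sigmoid output.
#'
#' @param omicFeatures DEG-indexed feature vector.
#' @param params list with `W1`, `b1`, `W2`, `b2`, `w3`, `b3`.
#' @param dropout dropout rate (training mode only).
#' @param train training mode flag.
#' @return MSI probability in (0, 1).
#' @export
dmlpForward <- function(omicFeatures, params, dropout = 0.1, train = FALSE) {
  if (ncol(params$W1) != length(omicFeatures))
    stop("omic feature vector does not match the model input width")
  z1 <- as.vector(params$W1 %*% omicFeatures) + params$b1
  r1 <- pmax(z1, 0) * .dropoutMask(length(z1), dropout, train)
  z2 <- as.vector(params$W2 %*% r1) + params$b2
  r2 <- pmax(z2, 0) * .dropoutMask(length(z2), dropout, train)
  .sigmoid(sum(params$w3 * r2) + params$b3)
}
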