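#' Validate or compute tile embeddings
#'
#' The package consumes precomputed 2048-d tile embeddings (the
#' global-average-pooled output of a 50-layer residual convolutional
#' backbone). Precomputed matrices are validated (width, finiteness) and
#' passed through unchanged. Raw tile arrays are only supported through a
#' registered backbone plugin -- a function mapping an image batch to an
#' `M x 2048` matrix -- which the package does not ship.
#'
#' @param tiles `M x 2048` numeric matrix of precomputed embeddings, or a
#'   raw image batch when `backbone` is supplied.
#' @param backbone optional plugin function for raw tiles.
#' @param embedDim expected embedding width (2048).
#' @return `M x 2048` numeric matrix.
#' @export
embedTiles <- function(tiles, backbone = NULL, embedDim = 2048L) {
  if (!is.matrix(tiles) || !is.numeric(tiles)) {
    if (is.null(backbone))
      stop("backbone unavailable: raw tiles require a registered ",
           "backbone plugin; supply precomputed embeddings instead")
    tiles <- backbone(tiles)
  }
  if (ncol(tiles) != embedDim)
    stop("tile embeddings must have width ", embedDim,
         ", got ", ncol(tiles))
  if (any(!is.finite(tiles)))
    stop("tile embeddings contain non-finite values")
  tiles
}

#' Gated-attention MIL parameters
#'
#' Random initialization (Glorot uniform weights, zero biases) for the
#' instance projection (2048 -> 512) and the gated attention branch with
#' hidden dimension `L`: `V_a`, `U_a` (`L x 512`) and `w_a` (`L`).
#'
#' @param L attention hidden dimension (default 256).
#' @param inputDim embedding width (2048).
#' @param projDim instance dimension after projection (512).
#' @return list with `Wp`, `bp`, `Va`, `Ua`, `wa`.
#' @export
gatedAttentionParams <- function(L = 256L, inputDim = 2048L, projDim = 512L) {
  list(Wp = .glorot(projDim, inputDim), bp = numeric(projDim),
       Va = .glorot(L, projDim), Ua = .glorot(L, projDim),
       wa = as.vector(.glorot(L, 1L)))
}

#' Project instances to the attention space
#'
#' Affine map of each tile embedding into the 512-d instance space:
#' `h_m = Wp x_m + bp`, applied row-wise.
#'
#' @param features `M x inputDim` matrix.
#' @param params list with `Wp` (`projDim x inputDim`) and `bp`.
#' @return `M x projDim` matrix `H` (rows `h_m`).
#' @export
projectInstances <- function(features, params) {
  stopifnot(ncol(features) == ncol(params$Wp))
  H <- tcrossprod(features, params$Wp)
  sweep(H, 2, params$bp, "+")
}

#' Gated attention scores over one bag
#'
#' Computes `logit_m = w_a . (tanh(V_a h_m) * sigm(U_a h_m))` for every
#' instance of one patient's bag and normalizes with a max-subtracted
#' softmax over the bag, so the weights are non-negative and sum to 1.
#' Bags never mix patients (batch size is 1 throughout).
#'
#' @param H `M x projDim` instance matrix.
#' @param params list with `Va`, `Ua`, `wa`.
#' @return attention weight vector `A` of length `M` on the simplex.
#' @export
gatedAttentionScores <- function(H, params) {
  stopifnot(nrow(H) >= 1L)
  G <- tanh(tcrossprod(H, params$Va)) * .sigmoid(tcrossprod(H, params$Ua))
  l <- as.vector(G %*% params$wa)
  l <- l - max(l)
  e <- exp(l)
  e / sum(e)
}

#' Attention-weighted pooling
#'
#' `h_patient = sum_m a_m h_m`: collapses one bag to a single patient-level
#' vector using the attention weights as convex coefficients.
#'
#' @param A attention weights on the simplex (length `M`).
#' @param H `M x projDim` instance matrix.
#' @return pooled vector of length `projDim`.
#' @export
attentionPool <- function(A, H) {
  stopifnot(length(A) == nrow(H))
  if (any(A < 0) || abs(sum(A) - 1) > 1e-6)
    stop("attention weights must be non-negative and sum to 1")
  as.vector(crossprod(H, A))
}

#' One-call gated-attention pooling of a bag
#'
#' Convenience composition of [projectInstances()],
#' [gatedAttentionScores()] and [attentionPool()].
#'
#' @param features `M x 2048` embedding matrix.
#' @param params [gatedAttentionParams()].
#' @return list with `H`, `A` and `hPatient`.
#' @export
amilPool <- function(features, params) {
  H <- projectInstances(features, params)
  A <- gatedAttentionScores(H, params)
  list(H = H, A = A, hPatient = attentionPool(A, H))
}

#' Attention-weight export
#'
#' Writes one patient's attention weights as a two-column CSV
#' (tile index, weight) for inspection.
#'
#' @param A attention weights.
#' @param path output CSV path.
#' @export
writeAttentionWeights <- function(A, path) {
  data.table::fwrite(data.frame(tile = seq_along(A), weight = A), path)
  invisible(path)
}
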