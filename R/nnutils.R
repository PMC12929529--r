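# Shared numerical primitives for the hand-authored networks.

.glorot <- function(fanOut, fanIn) {
  s <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanOut * fanIn, -s, s), fanOut, fanIn)
}

.sigmoid <- function(x) {
  x <- pmin(pmax(x, -30), 30)
  1 / (1 + exp(-x))
}

# binary cross entropy on one probability; clamped for log stability
.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# inverted dropout mask: scales kept units by 1/(1-rate) so evaluation
# needs no rescaling; rate 0 or eval mode -> no-op mask of 1s
.dropoutMask <- function(n, rate, train) {
  if (!train || rate <= 0) rep(1, n)
  else (runif(n) > rate) / (1 - rate)
}

# Adam state mirrors a named parameter list; moments live in interleaved
# single-precision raw buffers consumed by the C++ kernel
.adamInit <- function(params) {
  list(mv = lapply(params, function(p) raw(8L * length(p))),
       t = 0L)
}

# one fused in-place step over every parameter tensor (C++ kernel);
# params and moment buffers are private to the training loop so in-place
# mutation is safe
.adamStep <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    adam_step_(params[[nm]], state$mv[[nm]], g,
               lr, beta1, beta2, eps, wd, state$t)
  }
  state
}

# deep copy of a parameter list (the C++ Adam kernel mutates in place,
# so checkpoints must be forced copies)
.copyParams <- function(params) lapply(params, function(p) p + 0)
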