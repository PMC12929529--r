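#include <Rcpp.h>
#include <cmath>

// Fused in-place Adam update. `param` and the moment buffer `mv` are
// modified in place; both are private to the optimizer state (never
// handed to user code unduplicated), which trainModel() guarantees.
// The first and second moments are kept in single precision, interleaved
// [m0, v0, m1, v1, ...] in a raw buffer: moment noise is far below
// gradient noise, and halving the state traffic matters because the
// update is memory-bound. Weight decay is the classic L2-coupled form
// (added to the gradient before the moment updates), matching
// torch.optim.Adam's `weight_decay` semantics.
// [[Rcpp::export]]
void adam_step_(Rcpp::NumericVector param, Rcpp::RawVector mv,
                Rcpp::NumericVector grad,
                double lr, double beta1, double beta2, double eps,
                double wd, int t) {
  const R_xlen_t n = param.size();
  if (grad.size() != n || mv.size() != (R_xlen_t)(8 * n))
    Rcpp::stop("adam_step_: length mismatch");
  const double bc1 = 1.0 - std::pow(beta1, (double)t);
  const double bc2 = 1.0 - std::pow(beta2, (double)t);
  double *p = param.begin(), *g = grad.begin();
  float *s = reinterpret_cast<float *>(RAW(mv));
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i] + wd * p[i];
    const double m = beta1 * (double)s[2 * i] + (1.0 - beta1) * gi;
    const double v = beta2 * (double)s[2 * i + 1] + (1.0 - beta2) * gi * gi;
    s[2 * i] = (float)m;
    s[2 * i + 1] = (float)v;
    p[i] -= lr * (m / bc1) / (std::sqrt(v / bc2) + eps);
  }
}
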