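// Fused gradient-clipping + AdamW update over a list of parameter arrays.
// Called once per minibatch; updates pars, m and v in place (the training
// loop owns all three exclusively and deep-copies at checkpoints).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
void adamw_step_cpp(List pars, List grads, List m, List v,
                    int t, double lr, double weight_decay,
                    double clip_norm, double beta1, double beta2,
                    double eps) {
  const int k = grads.size();
  double sq = 0.0;
  for (int i = 0; i < k; ++i) {
    NumericVector g(grads[i]);
    const int n = g.size();
    const double *gp = g.begin();
    for (int j = 0; j < n; ++j) sq += gp[j] * gp[j];
  }
  const double total = std::sqrt(sq);
  const double scale = (R_finite(total) && total > clip_norm)
    ? clip_norm / total : 1.0;
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (int i = 0; i < k; ++i) {
    NumericVector g(grads[i]), p(pars[i]), mi(m[i]), vi(v[i]);
    const int n = g.size();
    double *gp = g.begin(), *pp = p.begin(), *mp = mi.begin(),
           *vp = vi.begin();
    for (int j = 0; j < n; ++j) {
      const double gj = gp[j] * scale;
      mp[j] = beta1 * mp[j] + (1.0 - beta1) * gj;
      vp[j] = beta2 * vp[j] + (1.0 - beta2) * gj * gj;
      const double step = (mp[j] / bc1) / (std::sqrt(vp[j] / bc2) + eps);
      pp[j] -= lr * step + lr * weight_decay * pp[j];
    }
  }
}
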