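#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive grid evaluation of fixed-LR Rescorla-Wagner comparators.
//
// For every learning-rate combination (lr1 for stable-run trials, lr2 for
// volatile-run trials; or a single shared lr when tie_lrs is true) the
// delta-rule trace f_{i+1} = f_i + lr * (o_i - f_i) is run over the
// concatenated trial sequence, and two model-evidence objectives are
// accumulated:
//   * bic_rs:   per-congruency least squares of RS on the pre-update f
//               (emission parameters profiled out), BIC = n ln(sigma2_hat)
//               + n_params ln(n) over valid-RS trials;
//   * bic_cong: trial likelihood 1 - |o - f| over all trials,
//               BIC = -2 sum(ln lik) + n_params ln(n).
// Matrices are laid out with lr2 on rows and lr1 on columns so a column-major
// which.min() in R realizes the smallest-(lr1, lr2) lexicographic tie-break.

// [[Rcpp::export]]
List lr_grid_evaluate(IntegerVector o, NumericVector rs, LogicalVector valid,
                      LogicalVector is_volatile, NumericVector lr1,
                      NumericVector lr2, double f0, bool tie_lrs,
                      int n_params) {
  const int n = o.size();
  const int g1 = lr1.size();
  const int g2 = tie_lrs ? 1 : lr2.size();
  if (n == 0) stop("empty trial sequence");
  if (g1 == 0 || (!tie_lrs && lr2.size() == 0)) stop("empty LR grid");

  int n_valid = 0;
  for (int i = 0; i < n; ++i) if (valid[i]) ++n_valid;
  if (n_valid < 2) stop("need at least 2 valid-RS trials");

  NumericMatrix bic_rs(g2, g1), bic_cong(g2, g1);

  for (int j = 0; j < g1; ++j) {
    for (int k = 0; k < g2; ++k) {
      const double l1 = lr1[j];
      const double l2 = tie_lrs ? lr1[j] : lr2[k];
      double f = f0;
      double conglik = 0.0;
      // per-congruency accumulators for RS ~ a + b f
      double nn[2] = {0, 0}, Sf[2] = {0, 0}, Sff[2] = {0, 0};
      double Sr[2] = {0, 0}, Srr[2] = {0, 0}, Sfr[2] = {0, 0};
      for (int i = 0; i < n; ++i) {
        const int oi = o[i];
        double lik = 1.0 - std::fabs((double)oi - f);
        if (lik < 1e-12) lik = 1e-12;
        conglik += std::log(lik);
        if (valid[i]) {
          const double r = rs[i];
          nn[oi] += 1.0; Sf[oi] += f; Sff[oi] += f * f;
          Sr[oi] += r; Srr[oi] += r * r; Sfr[oi] += f * r;
        }
        f += (is_volatile[i] ? l2 : l1) * ((double)oi - f);
      }
      double rss = 0.0;
      for (int c = 0; c < 2; ++c) {
        if (nn[c] < 2) { rss += Srr[c]; continue; }
        const double sxx = Sff[c] - Sf[c] * Sf[c] / nn[c];
        const double sxy = Sfr[c] - Sf[c] * Sr[c] / nn[c];
        double b = (sxx > 1e-12) ? sxy / sxx : 0.0;
        double a = (Sr[c] - b * Sf[c]) / nn[c];
        rss += Srr[c] - 2.0 * a * Sr[c] - 2.0 * b * Sfr[c] +
               nn[c] * a * a + 2.0 * a * b * Sf[c] + b * b * Sff[c];
      }
      double sigma2 = rss / n_valid;
      if (sigma2 < 1e-12) sigma2 = 1e-12;
      bic_rs(k, j) = n_valid * std::log(sigma2) +
                     n_params * std::log((double)n_valid);
      bic_cong(k, j) = -2.0 * conglik + n_params * std::log((double)n);
    }
  }
  return List::create(_["bic_rs"] = bic_rs, _["bic_cong"] = bic_cong);
}
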