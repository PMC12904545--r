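// Coherence-gated phasor accumulation for A-scan synthesis.
//
// For each reference delay L_ref(j):
//   U(j) = sum_i sqrt(W_i) * G(dL_ij) * exp(i * 2*pi * dL_ij / lambda),
//   dL_ij = L_i - L_ref(j),  G(d) = exp(-4 ln2 (d/lc)^2).
// Contributions beyond |dL| > cutoff*lc are dropped (the Gaussian gate
// is < 1e-30 at 5 lc); reference delays must be sorted increasing.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".phasor_sum")]]
List phasor_sum(NumericVector pathlength_um, NumericVector weight,
                NumericVector lref_um, double lambda_um, double lc_um,
                double cutoff = 6.0) {
  const int np = pathlength_um.size();
  const int nj = lref_um.size();
  if (weight.size() != np) stop("pathlength and weight lengths differ");
  for (int j = 1; j < nj; ++j)
    if (lref_um[j] < lref_um[j - 1])
      stop("reference delays must be sorted increasing");

  std::vector<double> re(nj, 0.0), im(nj, 0.0);
  const double four_ln2 = 4.0 * std::log(2.0);
  const double k0 = 2.0 * M_PI / lambda_um;
  const double win = cutoff * lc_um;
  const double *lr = REAL(lref_um);

  for (int i = 0; i < np; ++i) {
    const double L = pathlength_um[i];
    const double a0 = std::sqrt(weight[i]);
    const int j0 = std::lower_bound(lr, lr + nj, L - win) - lr;
    const int j1 = std::upper_bound(lr, lr + nj, L + win) - lr;
    for (int j = j0; j < j1; ++j) {
      const double d = L - lr[j];
      const double u = d / lc_um;
      const double amp = a0 * std::exp(-four_ln2 * u * u);
      const double ph = k0 * d;
      re[j] += amp * std::cos(ph);
      im[j] += amp * std::sin(ph);
    }
  }

  NumericVector raw(nj), env(nj);
  for (int j = 0; j < nj; ++j) {
    raw[j] = re[j];
    env[j] = std::sqrt(re[j] * re[j] + im[j] * im[j]);
  }
  return List::create(_["raw"] = raw, _["envelope"] = env);
}
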