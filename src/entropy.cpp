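#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Approximate and sample entropy (embedding m, Chebyshev distance) from a
// single O(n^2) template-pair sweep. Written in C++ because per-channel
// calls number in the thousands for a cohort-scale feature extraction.
//
// ApEn: Phi_m - Phi_{m+1}, Phi_m = mean_i log(C_i / n_templates) with
// self-matches included. SampEn: -log(A/B) over distinct pairs, templates
// restricted so the (m+1)-th element exists; 0 when A or B is empty.

// [[Rcpp::export(name = ".entropies_cpp")]]
NumericVector entropies_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  NumericVector out(2);
  if (n <= m + 1 || r <= 0.0) return out;
  int nt2 = n - m + 1; // templates of length m
  int nt3 = n - m;     // templates of length m + 1
  std::vector<int> c2(nt2, 0), c3(nt3, 0);
  long long A = 0, B = 0;
  for (int i = 0; i < nt2 - 1; ++i) {
    for (int j = i + 1; j < nt2; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++c2[i]; ++c2[j];
      if (j < nt3) { // i < j < nt3: both (m+1)-templates exist
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) {
          ++A; ++c3[i]; ++c3[j];
        }
      }
    }
  }
  double phi2 = 0.0, phi3 = 0.0;
  for (int i = 0; i < nt2; ++i)
    phi2 += std::log((double)(c2[i] + 1) / (double)nt2);
  phi2 /= (double)nt2;
  for (int i = 0; i < nt3; ++i)
    phi3 += std::log((double)(c3[i] + 1) / (double)nt3);
  phi3 /= (double)nt3;
  out[0] = phi2 - phi3;                                  // ApEn
  out[1] = (A == 0 || B == 0) ? 0.0 : -std::log((double)A / (double)B);
  return out;
}
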