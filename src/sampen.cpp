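#include <Rcpp.h>
using namespace Rcpp;

// Template-pair counts for sample entropy.
//
// B = number of unordered pairs (i, j), i < j, of m-length templates whose
// Chebyshev distance is <= r; A = the same for (m+1)-length templates.
// Both counts run over template start indices 1..N-m (the Richman-Moorman
// convention, self-matches excluded), so every (m+1)-match is also an
// m-match and -log(A/B) >= 0 whenever defined.
//
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;            // number of (m+1)-capable template starts
  double A = 0.0, B = 0.0;
  if (nt < 2) return NumericVector::create(0.0, 0.0);
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dmax = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dmax) dmax = d;
        if (dmax > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double d = std::fabs(x[i + m] - x[j + m]);
      if (d > dmax) dmax = d;
      if (dmax <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
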