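#include <Rcpp.h>
using namespace Rcpp;

// Template-pair counts for sample entropy.
// Templates start at i = 0..n-m-1 so that both the m- and (m+1)-point
// template exist for every index; pairs are unordered with i < j
// (self-matches excluded). B counts pairs whose m-point templates lie
// within Chebyshev distance r, A the same for m+1 points. SampEn is
// -log(A/B); the ratio is invariant to the ordered/unordered convention.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
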