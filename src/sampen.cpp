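#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy of a series: -ln(A/B), where B counts pairs of length-m
// templates matching within Chebyshev tolerance r, and A the same for
// length m+1; self-matches excluded. Degenerate cases (A == 0 or B == 0)
// return log(n) as a finite cap.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for sample entropy");
  long long A = 0, B = 0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        d = std::fabs(x[i + k] - x[j + k]);
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  if (B == 0 || A == 0) return std::log((double) n);
  return -std::log((double) A / (double) B);
}
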