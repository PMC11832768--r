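#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy SampEn(m, r): -log(A / B) where B counts template pairs
// of length m and A pairs of length m+1 within Chebyshev distance r,
// excluding self-matches. Templates indexed over i = 0..n-m-1 for both
// lengths (the standard convention). Degenerate cases (r <= 0, too-short
// series, zero match counts) return 0 by package convention so every
// window feature stays finite.
// [[Rcpp::export]]
double sample_entropy_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1 || r <= 0.0) return 0.0;
  long long A = 0, B = 0;
  int N = n - m;  // number of (m+1)-length templates
  const double *p = REAL(x);
  if (m == 2) {  // hot path: the package default
    for (int i = 0; i < N - 1; ++i) {
      const double xi0 = p[i], xi1 = p[i + 1], xi2 = p[i + 2];
      for (int j = i + 1; j < N; ++j) {
        if (std::abs(xi0 - p[j]) > r) continue;
        if (std::abs(xi1 - p[j + 1]) > r) continue;
        ++B;
        if (std::abs(xi2 - p[j + 2]) <= r) ++A;
      }
    }
  } else {
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        bool match = true;
        for (int k = 0; k < m; ++k) {
          if (std::abs(p[i + k] - p[j + k]) > r) { match = false; break; }
        }
        if (!match) continue;
        ++B;
        if (std::abs(p[i + m] - p[j + m]) <= r) ++A;
      }
    }
  }
  if (A == 0 || B == 0) return 0.0;
  return -std::log((double)A / (double)B);
}
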