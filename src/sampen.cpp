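#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.
//
// Counts unordered pairs (i < j) of templates of length m (and m+1) that
// match under the Chebyshev (max-coordinate) distance within tolerance r.
// Templates are taken at every start i = 0..N-m-1 so that the (m+1)-point
// extension exists for all counted templates; self-matches are excluded by
// construction.  Counts can exceed 2^31 for long series, so they are
// accumulated in 64-bit integers and returned as doubles (exact up to 2^53).
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates with an (m+1)-th point
  if (nt < 2)
    stop("series too short for embedding dimension m");
  long long A = 0, B = 0;
  const double *v = REAL(x);
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      // cheap first-coordinate rejection dominates the run time
      if (std::fabs(v[i] - v[j]) > r) continue;
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(v[i + k] - v[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      if (std::fabs(v[i + m] - v[j + m]) <= r) ++A;
    }
  }
  return List::create(Named("A") = (double)A, Named("B") = (double)B);
}

// Bubble-sort swap counts for every embedded vector of length m.
// Equal adjacent elements are not swapped (ties contribute no swaps), which
// keeps counts stable on quantized data.  Equivalent to the number of
// inversions under strict ordering.
// [[Rcpp::export]]
IntegerVector bubble_swap_counts(NumericVector x, int m) {
  const int n = x.size();
  const int nv = n - m + 1;
  if (nv < 1) stop("series too short for embedding dimension m");
  IntegerVector out(nv);
  std::vector<double> w(m);
  for (int i = 0; i < nv; ++i) {
    for (int k = 0; k < m; ++k) w[k] = x[i + k];
    int swaps = 0;
    // classic bubble sort with early exit
    for (int pass = m - 1; pass > 0; --pass) {
      bool swapped = false;
      for (int k = 0; k < pass; ++k) {
        if (w[k] > w[k + 1]) {
          std::swap(w[k], w[k + 1]);
          ++swaps;
          swapped = true;
        }
      }
      if (!swapped) break;
    }
    out[i] = swaps;
  }
  return out;
}
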