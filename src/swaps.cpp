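#include <Rcpp.h>
using namespace Rcpp;

// Continuous diagonal transfer within all-non-zero 2x2 submatrices:
// preserves row totals, column totals and the occurrence pattern exactly.
// The transfer amount is uniform on (-min(b,c), min(a,d)), leaving all
// four cells strictly positive.
// [[Rcpp::export]]
NumericMatrix abundance_swap_walk(NumericMatrix m, int attempts) {
  NumericMatrix out = clone(m);
  int nr = out.nrow(), nc = out.ncol();
  if (nr < 2 || nc < 2) return out;
  for (int t = 0; t < attempts; ++t) {
    int i = (int)(unif_rand() * nr), k = (int)(unif_rand() * (nr - 1));
    if (k >= i) ++k;
    int j = (int)(unif_rand() * nc), l = (int)(unif_rand() * (nc - 1));
    if (l >= j) ++l;
    double a = out(i, j), b = out(i, l), c = out(k, j), d = out(k, l);
    if (a <= 0 || b <= 0 || c <= 0 || d <= 0) continue;
    double lo = -std::min(b, c), hi = std::min(a, d);
    double x = lo + unif_rand() * (hi - lo);
    if (a - x <= 0 || d - x <= 0 || b + x <= 0 || c + x <= 0) continue;
    out(i, j) = a - x;
    out(i, l) = b + x;
    out(k, j) = c + x;
    out(k, l) = d - x;
  }
  return out;
}

// Count all-non-zero 2x2 submatrices (candidates for abundance transfer).
// [[Rcpp::export]]
int count_swappable_dense(NumericMatrix m) {
  int nr = m.nrow(), nc = m.ncol(), cnt = 0;
  for (int i = 0; i < nr - 1; ++i)
    for (int k = i + 1; k < nr; ++k)
      for (int j = 0; j < nc - 1; ++j)
        for (int l = j + 1; l < nc; ++l)
          if (m(i, j) > 0 && m(i, l) > 0 && m(k, j) > 0 && m(k, l) > 0)
            ++cnt;
  return cnt;
}
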