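#include <Rcpp.h>
#include "bias.h"
using namespace Rcpp;

// Accumulate hills (columns: centerA, centerB, sigmaA, sigmaB, height) onto an
// existing grid, in place. The caller owns the matrix and is responsible for
// copying if value semantics are needed.
// [[Rcpp::export]]
void cpp_deposit_hills(NumericMatrix grid, double lo, double spacing,
                       NumericMatrix hills) {
  if (grid.nrow() != grid.ncol()) stop("bias grid must be square");
  GridSpec g{lo, spacing, (int)grid.nrow()};
  double* v = REAL(grid);
  for (int k = 0; k < hills.nrow(); ++k) {
    if (hills(k, 2) <= 0 || hills(k, 3) <= 0) stop("hill widths must be > 0");
    deposit_hill_images(v, g, hills(k, 0), hills(k, 1),
                        hills(k, 2), hills(k, 3), hills(k, 4));
  }
}

// Time-averaged bias reconstructed from a hill log: the instantaneous bias
// V(t) is the sum of all hills deposited at times <= t; the effective bias is
// the mean of V over the sample times. Hills must be time-sorted; sample
// times ascending. Columns of `hills`: time, centerA, centerB, sigmaA,
// sigmaB, height.
// [[Rcpp::export]]
NumericMatrix cpp_bias_time_average(int n, double lo, double spacing,
                                    NumericMatrix hills,
                                    NumericVector sample_times) {
  GridSpec g{lo, spacing, n};
  const int ns = sample_times.size();
  if (ns < 1) stop("need at least one sample time");
  std::vector<double> cur((size_t)n * n, 0.0), acc((size_t)n * n, 0.0);
  int k = 0;
  for (int s = 0; s < ns; ++s) {
    if (s > 0 && sample_times[s] < sample_times[s - 1])
      stop("sample times must be ascending");
    while (k < hills.nrow() && hills(k, 0) <= sample_times[s]) {
      deposit_hill_images(cur.data(), g, hills(k, 1), hills(k, 2),
                          hills(k, 3), hills(k, 4), hills(k, 5));
      ++k;
    }
    for (size_t i = 0; i < cur.size(); ++i) acc[i] += cur[i];
  }
  NumericMatrix out(n, n);
  for (size_t i = 0; i < cur.size(); ++i) out[i] = acc[i] / ns;
  return out;
}

// Bilinear lookup of a square grid at coordinate pairs (clamped to the hull).
// [[Rcpp::export]]
NumericVector cpp_bilinear_lookup(NumericMatrix grid, double lo, double spacing,
                                  NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("coordinate vectors differ in length");
  GridSpec g{lo, spacing, (int)grid.nrow()};
  const double* v = REAL(grid);
  NumericVector out(a.size());
  double val, da, db;
  for (int i = 0; i < a.size(); ++i) {
    bilinear_eval(v, g, a[i], b[i], &val, &da, &db);
    out[i] = val;
  }
  return out;
}
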