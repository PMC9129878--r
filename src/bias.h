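#pragma once
#include <vector>
#include <cmath>
#include <algorithm>

// Square lattice over (zetaA, zetaB) in Angstrom, values in kcal/mol.
// Column-major: value(i,j) = v[i + n*j], zeta_i = lo + i*spacing.
struct GridSpec {
  double lo;
  double spacing;
  int n;
  double hi() const { return lo + spacing * (n - 1); }
};

// Up to two disjoint index intervals covering +/- nsig*sigma around c and -c.
inline int hill_ranges(const GridSpec& g, double c, double sigma, double nsig,
                       int lo_idx[2], int hi_idx[2]) {
  const double w = nsig * sigma;
  double a0 = c - w, a1 = c + w;       // window around the hill centre
  double b0 = -c - w, b1 = -c + w;     // window around its mirror image
  if (a0 > b0) { std::swap(a0, b0); std::swap(a1, b1); }
  int nr;
  double lo0, hi0, lo1 = 0.0, hi1 = 0.0;
  if (b0 <= a1) {            // overlapping -> single merged interval
    nr = 1; lo0 = a0; hi0 = std::max(a1, b1);
  } else {
    nr = 2; lo0 = a0; hi0 = a1; lo1 = b0; hi1 = b1;
  }
  int out = 0;
  const double los[2] = {lo0, lo1}, his[2] = {hi0, hi1};
  for (int r = 0; r < nr; ++r) {
    int i0 = (int)std::ceil((los[r] - g.lo) / g.spacing);
    int i1 = (int)std::floor((his[r] - g.lo) / g.spacing);
    i0 = std::max(i0, 0);
    i1 = std::min(i1, g.n - 1);
    if (i0 <= i1) { lo_idx[out] = i0; hi_idx[out] = i1; ++out; }
  }
  return out;
}

// One hill plus its boundary images: the deposited field factorises as
//   h * [g(a - cA) + g(a + cA)] * [g(b - cB) + g(b + cB)]
// i.e. the main Gaussian, one mirror per CV dimension across zeta = 0, and the
// double mirror. This makes the bias gradient normal to each boundary vanish.
inline void deposit_hill_images(double* v, const GridSpec& g,
                                double cA, double cB, double sA, double sB,
                                double h, double nsig = 6.0) {
  int aLo[2], aHi[2], bLo[2], bHi[2];
  const int nra = hill_ranges(g, cA, sA, nsig, aLo, aHi);
  const int nrb = hill_ranges(g, cB, sB, nsig, bLo, bHi);
  const double ia = 1.0 / (2.0 * sA * sA), ib = 1.0 / (2.0 * sB * sB);
  for (int ra = 0; ra < nra; ++ra) {
    for (int i = aLo[ra]; i <= aHi[ra]; ++i) {
      const double x = g.lo + i * g.spacing;
      const double da = x - cA, ma = x + cA;
      const double fa = std::exp(-da * da * ia) + std::exp(-ma * ma * ia);
      for (int rb = 0; rb < nrb; ++rb) {
        for (int j = bLo[rb]; j <= bHi[rb]; ++j) {
          const double y = g.lo + j * g.spacing;
          const double db = y - cB, mb = y + cB;
          const double fb = std::exp(-db * db * ib) + std::exp(-mb * mb * ib);
          v[i + (size_t)g.n * j] += h * fa * fb;
        }
      }
    }
  }
}

// Bilinear interpolation of the grid and its gradient; coordinates are clamped
// to the lattice hull (zero gradient contribution outside).
inline void bilinear_eval(const double* v, const GridSpec& g,
                          double a, double b,
                          double* val, double* dva, double* dvb) {
  const double hi = g.hi();
  bool clampA = false, clampB = false;
  if (a <= g.lo) { a = g.lo; clampA = true; }
  if (a >= hi)   { a = hi;   clampA = true; }
  if (b <= g.lo) { b = g.lo; clampB = true; }
  if (b >= hi)   { b = hi;   clampB = true; }
  int i = (int)std::floor((a - g.lo) / g.spacing);
  int j = (int)std::floor((b - g.lo) / g.spacing);
  i = std::min(i, g.n - 2); j = std::min(j, g.n - 2);
  const double fa = (a - (g.lo + i * g.spacing)) / g.spacing;
  const double fb = (b - (g.lo + j * g.spacing)) / g.spacing;
  const size_t n = (size_t)g.n;
  const double v00 = v[i + n * j],       v10 = v[i + 1 + n * j];
  const double v01 = v[i + n * (j + 1)], v11 = v[i + 1 + n * (j + 1)];
  *val = (1 - fa) * (1 - fb) * v00 + fa * (1 - fb) * v10 +
         (1 - fa) * fb * v01 + fa * fb * v11;
  *dva = clampA ? 0.0 : (((1 - fb) * (v10 - v00) + fb * (v11 - v01)) / g.spacing);
  *dvb = clampB ? 0.0 : (((1 - fa) * (v01 - v00) + fa * (v11 - v10)) / g.spacing);
}
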