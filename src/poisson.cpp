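#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Finite-difference solve of div(eps grad phi) = -4 pi k q on a regular
// lattice (k = 332.0636 kcal A / (mol e^2); q in e; spacing in A; phi in
// kcal/(mol e)). Zero ionic strength. Dirichlet boundary values are taken
// from `phi` as passed in; interior values serve as the initial guess.
// Face permittivities are arithmetic means of the adjacent nodes.
// Gauss-Seidel with successive over-relaxation; converges when the largest
// update falls below `tol`.
// [[Rcpp::export]]
List cpp_solve_poisson(NumericVector eps, NumericVector rho, NumericVector phi,
                       int nx, int ny, int nz, double spacing,
                       double tol, int max_iter, double omega) {
  const size_t n = (size_t)nx * ny * nz;
  if ((size_t)eps.size() != n || (size_t)rho.size() != n ||
      (size_t)phi.size() != n)
    stop("array sizes disagree with grid dimensions");
  const double kcoul = 332.0636;
  const double fourpik = 4.0 * M_PI * kcoul;
  std::vector<double> p(phi.begin(), phi.end());
  const double* e = REAL(eps);
  const double* q = REAL(rho);
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;

  double maxd = 0.0;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    maxd = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        size_t idx = sx + sy * j + sz * k;
        for (int i = 1; i < nx - 1; ++i, ++idx) {
          const double ec = e[idx];
          const double exm = 0.5 * (ec + e[idx - sx]);
          const double exp_ = 0.5 * (ec + e[idx + sx]);
          const double eym = 0.5 * (ec + e[idx - sy]);
          const double eyp = 0.5 * (ec + e[idx + sy]);
          const double ezm = 0.5 * (ec + e[idx - sz]);
          const double ezp = 0.5 * (ec + e[idx + sz]);
          const double denom = exm + exp_ + eym + eyp + ezm + ezp;
          const double rhs = exm * p[idx - sx] + exp_ * p[idx + sx] +
                             eym * p[idx - sy] + eyp * p[idx + sy] +
                             ezm * p[idx - sz] + ezp * p[idx + sz] +
                             fourpik * q[idx] / spacing;
          const double pn = (1.0 - omega) * p[idx] + omega * rhs / denom;
          const double d = std::fabs(pn - p[idx]);
          if (d > maxd) maxd = d;
          p[idx] = pn;
        }
      }
    }
    if (maxd < tol) break;
  }
  if (maxd >= tol)
    stop("Poisson solver did not converge: max update %g after %d iterations",
         maxd, max_iter);
  NumericVector out(p.begin(), p.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["phi"] = out, _["iterations"] = it,
                      _["max_update"] = maxd);
}
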