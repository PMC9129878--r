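#include <Rcpp.h>
#include <random>
#include "bias.h"
using namespace Rcpp;

namespace {

const double KB = 0.001987204259; // kcal/(mol K)

// Soft-min proximity zeta = beta / ln(sum_k exp(beta/(|dz_k|+C))) - C and its
// derivative with respect to each ion z, evaluated with log-sum-exp.
struct SoftMin {
  double beta, C;
  double value(const std::vector<double>& dz) const {
    double m = -1e300;
    for (double d : dz) m = std::max(m, beta / (std::fabs(d) + C));
    double s = 0.0;
    for (double d : dz) s += std::exp(beta / (std::fabs(d) + C) - m);
    return beta / (m + std::log(s)) - C;
  }
  // value + d(zeta)/dz_k for all k
  double value_grad(const std::vector<double>& dz, std::vector<double>& grad) const {
    const size_t n = dz.size();
    double m = -1e300;
    for (double d : dz) m = std::max(m, beta / (std::fabs(d) + C));
    double s = 0.0;
    std::vector<double> e(n);
    for (size_t k = 0; k < n; ++k) {
      e[k] = std::exp(beta / (std::fabs(dz[k]) + C) - m);
      s += e[k];
    }
    const double L = m + std::log(s);
    for (size_t k = 0; k < n; ++k) {
      const double dk = std::fabs(dz[k]) + C;
      const double w = e[k] / s;
      const double sgn = (dz[k] >= 0.0) ? 1.0 : -1.0;
      grad[k] = (beta * beta) * w / (L * L * dk * dk) * sgn;
    }
    return beta / L - C;
  }
};

double schedule_height_ps(double t_ps, double h0, double hpk,
                          double t_rise_ps, double t_decay_ps) {
  if (t_ps <= 0.0) return h0;
  if (t_ps < t_rise_ps) return h0 + (hpk - h0) * t_ps / t_rise_ps;
  if (t_ps < t_decay_ps)
    return hpk - (hpk - h0) * (t_ps - t_rise_ps) / (t_decay_ps - t_rise_ps);
  return h0;
}

} // namespace

// Multiple-walker overdamped Langevin dynamics of non-interacting ions in a
// radially confined cylindrical pore with a Gaussian axial barrier, optional
// constant axial field, and optional metadynamics on the two soft-min CVs.
// All walkers share one bias grid (modified in place). Deterministic given
// `seed`: walker w uses RNG stream seed + w.
// [[Rcpp::export]]
List cpp_simulate_toy_pore(int n_ions, int n_walkers, int n_steps, double dt,
                           double D, double temperature, double box_z,
                           bool periodic_z, double pore_radius, double k_conf,
                           double U0, double barrier_width, double Ez,
                           double center_a_z, double center_b_z,
                           bool biased, double beta, double C_reg,
                           double sigma_hill, int hill_every, double h0,
                           double h_peak, double t_rise_ps, double t_decay_ps,
                           NumericMatrix bias, double grid_lo,
                           double grid_spacing, int snap_stride, int seed) {
  if (n_ions < 1 || n_walkers < 1 || n_steps < 1) stop("empty simulation");
  const double kT = KB * temperature;
  const double mob = D / kT;            // mobility, A^2/(ps kcal/mol)
  const double noise = std::sqrt(2.0 * D * dt);
  const double half_z = box_z / 2.0;
  const double iw2 = 1.0 / (barrier_width * barrier_width);
  GridSpec g{grid_lo, grid_spacing, (int)bias.nrow()};
  double* bv = REAL(bias);
  SoftMin sm{beta, C_reg};

  // state: per walker, per ion
  std::vector<std::vector<double>> X(n_walkers), Y(n_walkers), Z(n_walkers);
  std::vector<std::mt19937_64> rng;
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int w = 0; w < n_walkers; ++w) {
    rng.emplace_back((uint64_t)seed + (uint64_t)w);
    X[w].resize(n_ions); Y[w].resize(n_ions); Z[w].resize(n_ions);
    for (int k = 0; k < n_ions; ++k) {
      // uniform in the confining cylinder, uniform along z
      const double r = pore_radius * std::sqrt(unif(rng[w]));
      const double th = 2.0 * M_PI * unif(rng[w]);
      X[w][k] = r * std::cos(th);
      Y[w][k] = r * std::sin(th);
      Z[w][k] = (unif(rng[w]) - 0.5) * box_z;
    }
  }

  const int n_snap = n_steps / std::max(snap_stride, 1);
  const int ncol = 4 + 2 * n_ions;
  NumericMatrix snaps((R_xlen_t)n_snap * n_walkers, ncol);
  const int n_hill_steps = biased ? n_steps / std::max(hill_every, 1) : 0;
  NumericMatrix hills((R_xlen_t)n_hill_steps * n_walkers, 7);
  R_xlen_t snap_row = 0, hill_row = 0;

  std::vector<double> dzA(n_ions), dzB(n_ions), gA(n_ions), gB(n_ions);

  for (int step = 0; step < n_steps; ++step) {
    const double t_now = (step + 1) * dt;
    for (int w = 0; w < n_walkers; ++w) {
      double dVa = 0.0, dVb = 0.0, val = 0.0;
      double zA = 0.0, zB = 0.0;
      if (biased) {
        for (int k = 0; k < n_ions; ++k) {
          dzA[k] = Z[w][k] - center_a_z;
          dzB[k] = Z[w][k] - center_b_z;
        }
        zA = sm.value_grad(dzA, gA);
        zB = sm.value_grad(dzB, gB);
        bilinear_eval(bv, g, zA, zB, &val, &dVa, &dVb);
      }
      for (int k = 0; k < n_ions; ++k) {
        const double z = Z[w][k];
        // axial forces: barrier, field, bias
        double fz = U0 * z * iw2 * std::exp(-0.5 * z * z * iw2) + Ez;
        if (biased) fz -= dVa * gA[k] + dVb * gB[k];
        // radial confinement
        double fx = 0.0, fy = 0.0;
        const double R = std::sqrt(X[w][k] * X[w][k] + Y[w][k] * Y[w][k]);
        if (R > pore_radius) {
          const double fr = -k_conf * (R - pore_radius) / R;
          fx = fr * X[w][k];
          fy = fr * Y[w][k];
        }
        X[w][k] += mob * fx * dt + noise * gauss(rng[w]);
        Y[w][k] += mob * fy * dt + noise * gauss(rng[w]);
        double zn = z + mob * fz * dt + noise * gauss(rng[w]);
        if (periodic_z) {
          zn -= box_z * std::floor(zn / box_z + 0.5);  // wrap to [-L/2, L/2)
        } else {
          while (zn > half_z || zn < -half_z) {        // reflecting walls
            if (zn > half_z) zn = box_z - zn; else zn = -box_z - zn;
          }
        }
        Z[w][k] = zn;
      }
    }

    if (biased && ((step + 1) % hill_every == 0)) {
      const double h = schedule_height_ps(t_now, h0, h_peak, t_rise_ps, t_decay_ps);
      for (int w = 0; w < n_walkers; ++w) {
        for (int k = 0; k < n_ions; ++k) {
          dzA[k] = Z[w][k] - center_a_z;
          dzB[k] = Z[w][k] - center_b_z;
        }
        const double zA = sm.value(dzA), zB = sm.value(dzB);
        deposit_hill_images(bv, g, zA, zB, sigma_hill, sigma_hill, h);
        hills(hill_row, 0) = t_now;
        hills(hill_row, 1) = zA;
        hills(hill_row, 2) = zB;
        hills(hill_row, 3) = sigma_hill;
        hills(hill_row, 4) = sigma_hill;
        hills(hill_row, 5) = h;
        hills(hill_row, 6) = w;
        ++hill_row;
      }
    }

    if ((step + 1) % snap_stride == 0) {
      for (int w = 0; w < n_walkers; ++w) {
        double zA = NA_REAL, zB = NA_REAL;
        for (int k = 0; k < n_ions; ++k) {
          dzA[k] = Z[w][k] - center_a_z;
          dzB[k] = Z[w][k] - center_b_z;
        }
        zA = sm.value(dzA);
        zB = sm.value(dzB);
        snaps(snap_row, 0) = t_now;
        snaps(snap_row, 1) = w;
        snaps(snap_row, 2) = zA;
        snaps(snap_row, 3) = zB;
        for (int k = 0; k < n_ions; ++k) {
          snaps(snap_row, 4 + k) = Z[w][k];
          snaps(snap_row, 4 + n_ions + k) =
            std::sqrt(X[w][k] * X[w][k] + Y[w][k] * Y[w][k]);
        }
        ++snap_row;
      }
    }
  }
  return List::create(_["snapshots"] = snaps, _["hills"] = hills);
}

// Direct soft-min evaluation used by the R wrappers.
// [[Rcpp::export]]
double cpp_softmin(NumericVector dz, double beta, double C_reg) {
  std::vector<double> v(dz.begin(), dz.end());
  SoftMin sm{beta, C_reg};
  return sm.value(v);
}
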