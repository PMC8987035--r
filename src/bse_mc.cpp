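// Monte-Carlo electron trajectories in a silicon slab.
//
// Single-scattering model: screened-Rutherford elastic events with
// exponential free paths, continuous (Bethe/Berger-Seltzer) energy loss
// between events. Each electron uses its own counter-based RNG substream
// derived from (seed, electron index), so results do not depend on
// execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double MC2 = 510.99895;     // electron rest energy, keV
static const double NA_CONST = 6.02214076e23;

// --- splitmix64 -> xorshift128+ per-electron substream ---------------------
struct SubRng {
  uint64_t s0, s1;
  explicit SubRng(uint64_t seed) {
    uint64_t z = seed;
    auto mix = [&z]() {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      return t ^ (t >> 31);
    };
    s0 = mix(); s1 = mix();
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  double unif() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    uint64_t r = s1 + y;
    return ((r >> 11) + 0.5) * (1.0 / 9007199254740992.0);  // in (0,1)
  }
};

// Relativistic (Berger-Seltzer) collision stopping power, keV/um, with the
// Joy-Luo effective ionization potential at low energy.
static double stopping_keV_um(double E, double Z, double A, double rho,
                              double J_keV) {
  double k = 0.731 + 0.0688 * std::log10(Z);
  double Jeff = J_keV / (1.0 + k * J_keV / E);
  double tau = E / MC2;
  double beta2 = 1.0 - 1.0 / ((1.0 + tau) * (1.0 + tau));
  double term = std::log(tau * tau * (tau + 2.0) /
                         (2.0 * (Jeff / MC2) * (Jeff / MC2)));
  double tp1 = tau + 1.0;
  double F = 1.0 - beta2 +
             (tau * tau / 8.0 - (2.0 * tau + 1.0) * std::log(2.0)) /
                 (tp1 * tp1);
  double mev_cm = 0.1535 * (Z * rho / (A * beta2)) * (term + F);
  return mev_cm / 10.0;  // MeV/cm -> keV/um
}

// screening parameter (Joy)
static inline double screen_alpha(double E, double Z) {
  return 3.4e-3 * std::pow(Z, 0.67) / E;
}

// screened-Rutherford total elastic cross-section, cm^2 (relativistic)
static double sigma_elastic(double E, double Z) {
  double a = screen_alpha(E, Z);
  double rel = (E + MC2) / (E + 2.0 * MC2);
  return 5.21e-21 * (Z / E) * (Z / E) * (4.0 * M_PI / (a * (1.0 + a))) *
         rel * rel;
}

// elastic mean free path, um
static double mfp_um(double E, double Z, double A, double rho) {
  double N = rho * NA_CONST / A;                   // atoms / cm^3
  return 1.0 / (N * sigma_elastic(E, Z)) * 1e4;
}

// [[Rcpp::export(name = ".bse_stopping_cpp")]]
NumericVector bse_stopping_cpp(NumericVector E, double Z, double A,
                               double rho, double J_keV) {
  NumericVector out(E.size());
  for (R_xlen_t i = 0; i < E.size(); ++i)
    out[i] = stopping_keV_um(E[i], Z, A, rho, J_keV);
  return out;
}

// [[Rcpp::export(name = ".bse_mfp_cpp")]]
NumericVector bse_mfp_cpp(NumericVector E, double Z, double A, double rho) {
  NumericVector out(E.size());
  for (R_xlen_t i = 0; i < E.size(); ++i)
    out[i] = mfp_um(E[i], Z, A, rho);
  return out;
}

// [[Rcpp::export(name = ".bse_simulate_cpp")]]
List bse_simulate_cpp(double E0, double thickness, double lateral, int n,
                      double Z, double A, double rho, double J_keV,
                      double cutoff, double seed) {
  int nb = 0, nt = 0, na = 0;
  std::vector<double> radii;
  double half = lateral / 2.0;
  for (int i = 0; i < n; ++i) {
    SubRng rng(static_cast<uint64_t>(seed) * 0x100000000ULL +
               static_cast<uint64_t>(i));
    double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1, E = E0;
    for (;;) {
      double lam = mfp_um(E, Z, A, rho);
      double s = -lam * std::log(rng.unif());
      double xp = x + ux * s, yp = y + uy * s, zp = z + uz * s;
      if (zp < 0.0) {  // re-exits entrance surface: backscattered
        double t = -z / (uz * s);
        double ex = x + ux * s * t, ey = y + uy * s * t;
        radii.push_back(std::sqrt(ex * ex + ey * ey));
        ++nb;
        break;
      }
      if (zp > thickness) { ++nt; break; }               // transmitted
      if (std::fabs(xp) > half || std::fabs(yp) > half) { ++na; break; }
      x = xp; y = yp; z = zp;
      E -= stopping_keV_um(E, Z, A, rho, J_keV) * s;
      if (E < cutoff) { ++na; break; }                   // absorbed
      double a = screen_alpha(E, Z);
      double R = rng.unif();
      double ct = 1.0 - 2.0 * a * R / (1.0 + a - R);
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double phi = 2.0 * M_PI * rng.unif();
      double cf = std::cos(phi), sf = std::sin(phi);
      if (std::fabs(uz) > 0.999999) {
        double sgn = uz > 0 ? 1.0 : -1.0;
        ux = st * cf; uy = st * sf; uz = sgn * ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = ux * ct + st * (ux * uz * cf - uy * sf) / den;
        double nuy = uy * ct + st * (uy * uz * cf + ux * sf) / den;
        double nuz = uz * ct - st * cf * den;
        ux = nux; uy = nuy; uz = nuz;
      }
      double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;
    }
  }
  return List::create(_["n_backscattered"] = nb, _["n_transmitted"] = nt,
                      _["n_absorbed"] = na,
                      _["exit_radii"] = NumericVector(radii.begin(),
                                                      radii.end()));
}
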