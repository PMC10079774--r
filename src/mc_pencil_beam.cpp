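#include <Rcpp.h>
#include <cmath>
#include <cstdint>

// Weighted-photon steady-state transport in a semi-infinite homogeneous
// medium, pencil beam incident at the origin. MCML-style: implicit weight
// deposit mu_a/mu_t at each interaction, deterministic partial-weight
// transmission at the mismatched boundary, Russian roulette for low
// weights. Detection is radial binning of the exit point, ignoring the
// exit angle.
//
// RNG: xoshiro256++ seeded via splitmix64 from the caller-supplied seed,
// so a run is bitwise reproducible from (seed, config) alone and
// independent of R's RNG state.

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0,1): never exactly 0 (safe for log())
  inline double runif() {
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }
};

inline double fresnel_unpol(double ct, double ni, double ne) {
  if (ct > 1.0) ct = 1.0;
  double st = std::sqrt(1.0 - ct * ct);
  double sin_r = ni / ne * st;
  if (sin_r >= 1.0) return 1.0;  // total internal reflection
  double ctr = std::sqrt(1.0 - sin_r * sin_r);
  double rs = (ni * ct - ne * ctr) / (ni * ct + ne * ctr);
  double rp = (ne * ct - ni * ctr) / (ne * ct + ni * ctr);
  return 0.5 * (rs * rs + rp * rp);
}

inline double sample_hg_cpp(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - s * s) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List mc_pencil_beam_cpp(double mu_a, double mu_s,
                              int phase_kind,          // 0 = HG, 1 = TTHG
                              double g_hg,
                              double w_fwd, double g_fwd, double g_bwd,
                              double n_in, double n_out,
                              double n_photons_d,
                              double bin_width, int n_bins,
                              double roulette_threshold,
                              double roulette_survival,
                              double seed) {
  const double mu_t = mu_a + mu_s;
  const double albedo = mu_s / mu_t;
  const bool matched = std::fabs(n_in - n_out) < 1e-12;
  const long long n_photons = (long long)n_photons_d;
  const double inv_mu_t = 1.0 / mu_t;

  Xoshiro256pp rng((uint64_t)seed);

  Rcpp::NumericVector bins(n_bins);
  double absorbed = 0.0, overflow = 0.0;
  double total_steps = 0.0;

  for (long long ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    bool alive = true;

    while (alive) {
      double s = -std::log(rng.runif()) * inv_mu_t;
      total_steps += 1.0;

      // propagate, handling (possibly repeated) boundary hits
      while (uz < 0.0 && z + s * uz < 0.0) {
        double s1 = -z / uz;              // path length to the surface
        x += s1 * ux; y += s1 * uy; z = 0.0;
        s -= s1;
        double ct = -uz;                  // internal incidence cosine
        double rf = matched ? 0.0 : fresnel_unpol(ct, n_in, n_out);
        double esc = w * (1.0 - rf);
        if (esc > 0.0) {
          double rho = std::sqrt(x * x + y * y);
          long long ib = (long long)(rho / bin_width);
          if (ib < n_bins) bins[(int)ib] += esc; else overflow += esc;
        }
        w *= rf;
        if (w <= 0.0) { alive = false; break; }
        uz = -uz;                         // specular re-entry
      }
      if (!alive) break;
      x += s * ux; y += s * uy; z += s * uz;

      // interaction: implicit absorption
      absorbed += w * (mu_a * inv_mu_t);
      w *= albedo;

      // roulette
      if (w < roulette_threshold) {
        if (rng.runif() < roulette_survival) w /= roulette_survival;
        else { alive = false; break; }
      }

      // scatter
      double ct;
      if (phase_kind == 0) {
        ct = sample_hg_cpp(g_hg, rng.runif());
      } else {
        double g = (rng.runif() < w_fwd) ? g_fwd : g_bwd;
        ct = sample_hg_cpp(g, rng.runif());
      }
      double st = std::sqrt(1.0 - ct * ct);
      double phi = 2.0 * M_PI * rng.runif();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = (uz >= 0.0 ? ct : -ct);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("bin_weights") = bins,
    Rcpp::Named("absorbed") = absorbed,
    Rcpp::Named("overflow") = overflow,
    Rcpp::Named("total_steps") = total_steps);
}
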