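// Photon-packet Monte-Carlo transport through a layered slab.
//
// Multilayer hop/drop/spin transport with Henyey-Greenstein scattering,
// probabilistic Fresnel boundaries and a disc detector above the top
// surface.  Internal units: micrometres for lengths, um^-1 for
// interaction coefficients (callers convert from mm^-1).
//
// The RNG is a self-contained xoshiro256++ seeded through splitmix64,
// so runs are reproducible bit-for-bit for a given seed regardless of
// R's global RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- RNG

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  inline double unif01() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // uniform in (0, 1] -- safe as a -log() argument
  inline double unif01_open0() {
    return 1.0 - unif01();
  }
};

// ------------------------------------------------------------- physics

// Exponential step law: s = -ln(u) / mu_t.
inline double step_length(double mu_t, double u) {
  return -std::log(u) / mu_t;
}

// Henyey-Greenstein deflection cosine by inverse-CDF sampling.
inline double hg_cosine(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double frac = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - frac * frac) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Unpolarized Fresnel reflectance for incidence cosine ci (> 0) going
// from index n1 into n2; *ct receives the refracted cosine (0 beyond
// the critical angle, where R = 1).
inline double fresnel_R(double n1, double n2, double ci, double *ct) {
  if (n1 == n2) { *ct = ci; return 0.0; }
  double si2 = 1.0 - ci * ci;
  double st2 = (n1 / n2) * (n1 / n2) * si2;  // sin^2 of refraction
  if (st2 >= 1.0) { *ct = 0.0; return 1.0; } // total internal reflection
  double c2 = std::sqrt(1.0 - st2);
  *ct = c2;
  if (ci > 0.9999999) {
    double r = (n1 - n2) / (n1 + n2);
    return r * r;
  }
  double rs = (n1 * ci - n2 * c2) / (n1 * ci + n2 * c2);
  double rp = (n1 * c2 - n2 * ci) / (n1 * c2 + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Rotate direction (ux,uy,uz) by deflection cosine ct and azimuth phi.
inline void spin(double ct, double phi, double &ux, double &uy, double &uz) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double denom = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
    double nz = -st * cp * denom + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
}

const double W_THRESHOLD = 1e-4;  // Russian-roulette threshold
const double W_CHANCE = 0.1;      // survival probability (weight x10)

} // namespace

// ------------------------------------------------------ exported helpers

//' @noRd
// [[Rcpp::export(name = ".mc_sample_step")]]
NumericVector mc_sample_step(double mu_t, NumericVector u) {
  if (!(mu_t > 0)) stop("mu_t must be > 0 (mu_t = 0 is a ballistic medium)");
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!(u[i] > 0.0) || u[i] > 1.0)
      stop("u must lie in (0, 1]");
    out[i] = step_length(mu_t, u[i]);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".mc_hg_cosine")]]
NumericVector mc_hg_cosine(double g, NumericVector u) {
  if (!(g > -1.0 && g < 1.0))
    stop("g must lie strictly inside (-1, 1) for sampling");
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cosine(g, u[i]);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".mc_fresnel")]]
List mc_fresnel(double n1, double n2, double cos_incident) {
  if (!(cos_incident > 0.0) || cos_incident > 1.0)
    stop("cos_incident must lie in (0, 1]");
  double ct;
  double R = fresnel_R(n1, n2, cos_incident, &ct);
  return List::create(_["R"] = R, _["cos_transmitted"] = ct);
}

//' @noRd
// [[Rcpp::export(name = ".mc_derive_seed")]]
double mc_derive_seed(double master_seed, double k) {
  uint64_t st = static_cast<uint64_t>(master_seed) * 0x9E3779B97F4A7C15ULL +
                static_cast<uint64_t>(k);
  uint64_t h = splitmix64(st);
  // keep within exact double range
  return static_cast<double>(h & ((1ULL << 53) - 1));
}

// ---------------------------------------------------------- transport

//' @noRd
// [[Rcpp::export(name = ".mc_run")]]
List mc_run(NumericMatrix layers,   // columns: thickness_um, mus_um, mua_um, g, n
            double n_above, double n_below,
            double det_radius_um, double det_height_um,
            double n_packets, double seed) {
  const int nl = layers.nrow();
  if (nl < 1) stop("at least one layer required");
  std::vector<double> ztop(nl), zbot(nl), mus(nl), mua(nl), mut(nl),
      gg(nl), nn(nl);
  double z0 = 0.0;
  for (int i = 0; i < nl; ++i) {
    double th = layers(i, 0);
    if (!(th > 0)) stop("layer thickness must be > 0");
    ztop[i] = z0; zbot[i] = z0 + th; z0 += th;
    mus[i] = layers(i, 1);
    mua[i] = layers(i, 2);
    mut[i] = mus[i] + mua[i];
    gg[i] = layers(i, 3);
    nn[i] = layers(i, 4);
  }

  const int64_t N = static_cast<int64_t>(n_packets);
  Xoshiro256pp rng(static_cast<uint64_t>(seed));

  int64_t n_back = 0, n_det = 0, n_scattered_any = 0, n_aborted = 0;
  std::vector<double> r_w, r_opl, r_x, r_y, r_ux, r_uy, r_uz;

  const double det_r2 = det_radius_um * det_radius_um;

  for (int64_t p = 0; p < N; ++p) {
    // launch at the top surface inside layer 0, pointing straight down
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0, opl = 0.0;
    int lay = 0;
    bool scattered = false;
    bool alive = true;

    while (alive) {
      if (!std::isfinite(x) || !std::isfinite(z) || !std::isfinite(uz)) {
        ++n_aborted;
        break;
      }
      double s;
      if (mut[lay] > 0.0) {
        s = step_length(mut[lay], rng.unif01_open0());
      } else {
        s = R_PosInf;  // ballistic medium: go straight to the boundary
      }

      // distance to the layer boundary along uz
      double db = R_PosInf;
      int to_boundary = 0;  // +1 bottom, -1 top
      if (uz > 0.0) { db = (zbot[lay] - z) / uz; to_boundary = 1; }
      else if (uz < 0.0) { db = (ztop[lay] - z) / uz; to_boundary = -1; }

      if (s >= db) {
        // hop to the boundary
        x += ux * db; y += uy * db; z += uz * db;
        opl += db * nn[lay];
        double n1 = nn[lay];
        double n2 = (to_boundary == 1)
                        ? (lay + 1 < nl ? nn[lay + 1] : n_below)
                        : (lay - 1 >= 0 ? nn[lay - 1] : n_above);
        double ci = std::fabs(uz), ct;
        double R = fresnel_R(n1, n2, ci, &ct);
        if (rng.unif01() < R) {
          uz = -uz;  // whole-packet specular reflection
        } else {
          // Snell refraction: transverse components scale by n1/n2
          double scale = n1 / n2;
          ux *= scale; uy *= scale;
          uz = (uz > 0.0 ? ct : -ct);
          if (to_boundary == 1) {
            if (lay + 1 < nl) { lay += 1; }
            else { alive = false; /* transmitted */ }
          } else {
            if (lay - 1 >= 0) { lay -= 1; }
            else {
              // backscattered out of the top surface
              alive = false;
              ++n_back;
              // straight-line continuation to the detector plane
              bool det = false;
              if (uz < 0.0) {
                double t = det_height_um / (-uz);
                double xd = x + ux * t, yd = y + uy * t;
                det = (xd * xd + yd * yd) <= det_r2;
              }
              if (det) {
                ++n_det;
                r_w.push_back(w);
                r_opl.push_back(opl);
                r_x.push_back(x); r_y.push_back(y);
                r_ux.push_back(ux); r_uy.push_back(uy); r_uz.push_back(uz);
              }
            }
          }
        }
      } else {
        // hop inside the layer, then drop & spin
        x += ux * s; y += uy * s; z += uz * s;
        opl += s * nn[lay];
        scattered = true;
        if (mua[lay] > 0.0) {
          w -= w * mua[lay] / mut[lay];
          if (w < W_THRESHOLD) {
            if (rng.unif01() < W_CHANCE) w /= W_CHANCE;
            else { alive = false; /* absorbed */ }
          }
        }
        if (alive) {
          double ct = (gg[lay] >= 1.0) ? 1.0
                                       : hg_cosine(gg[lay], rng.unif01());
          double phi = 2.0 * M_PI * rng.unif01();
          spin(ct, phi, ux, uy, uz);
        }
      }
    }
    if (scattered) ++n_scattered_any;
  }

  return List::create(
      _["n_launched"] = static_cast<double>(N),
      _["n_backscattered"] = static_cast<double>(n_back),
      _["n_detected"] = static_cast<double>(n_det),
      _["n_scattered"] = static_cast<double>(n_scattered_any),
      _["n_aborted"] = static_cast<double>(n_aborted),
      _["weight"] = wrap(r_w),
      _["optical_pathlength"] = wrap(r_opl),
      _["exit_x"] = wrap(r_x), _["exit_y"] = wrap(r_y),
      _["exit_ux"] = wrap(r_ux), _["exit_uy"] = wrap(r_uy),
      _["exit_uz"] = wrap(r_uz));
}
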