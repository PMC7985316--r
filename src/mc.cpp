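#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic counter-free RNG: xoshiro256++ seeded via splitmix64.
// Independent of R's RNG so every stochastic entry point is reproducible
// from its explicit integer seed alone.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
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
  // uniform in (0, 1]
  inline double runif_pos() {
    uint64_t u = next();
    return ((u >> 11) + 1.0) * 0x1.0p-53;
  }
  // uniform in [0, 1)
  inline double runif() {
    return (next() >> 11) * 0x1.0p-53;
  }
};

// Unpolarized Fresnel reflectance for incidence cosine cosi, n1 -> n2.
inline double fresnel_R(double n1, double n2, double cosi) {
  double sini2 = 1.0 - cosi * cosi;
  if (sini2 < 0) sini2 = 0;
  double sint = n1 / n2 * std::sqrt(sini2);
  if (sint >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

const double C_VACUUM = 0.0299792458;  // cm / ps

}  // namespace

//' @useDynLib rfaoptics, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".mc_slab_cpp")]]
List mc_slab_cpp(double thickness, double n_sample, double n_external,
                 double detector_radius, double mus, double mua,
                 double t0, double dt, int n_bins,
                 double n_photons, int seed,
                 double roulette_threshold = 0.0,
                 double roulette_survive = 0.1) {
  if (thickness <= 0 || mus <= 0 || n_photons < 1)
    stop("invalid Monte Carlo inputs");
  Xoshiro rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 12345ULL);

  NumericVector bins(n_bins);
  const double v = C_VACUUM / n_sample;            // cm/ps in the medium
  const double t_max = t0 + n_bins * dt;
  const double path_max = v * t_max;               // cannot score beyond this
  const long long N = static_cast<long long>(n_photons);

  double w_detected = 0, w_transmitted = 0, w_reflected = 0;
  double w_absorbed = 0, w_late = 0, w_roulette_net = 0;
  long long n_detected = 0;

  for (long long ip = 0; ip < N; ++ip) {
    double x = 0, y = 0, z = 0;
    double ux = 0, uy = 0, uz = 1;
    double w = 1.0, path = 0.0;
    bool alive = true;

    while (alive) {
      double s = -std::log(rng.runif_pos()) / mus;
      // distance to the slab face along the current direction
      double db = R_PosInf;
      int face = 0;  // +1 exit face (z = L), -1 entry face (z = 0)
      if (uz > 0) { db = (thickness - z) / uz; face = 1; }
      else if (uz < 0) { db = -z / uz; face = -1; }

      if (s < db) {
        // interior step + isotropic scatter
        x += ux * s; y += uy * s; z += uz * s; path += s;
        if (mua > 0) {
          double keep = std::exp(-mua * s);
          w_absorbed += w * (1.0 - keep);
          w *= keep;
        }
        if (path > path_max) { w_late += w; break; }
        double cz = 2.0 * rng.runif() - 1.0;
        double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
        double phi = 2.0 * M_PI * rng.runif();
        ux = sz * std::cos(phi); uy = sz * std::sin(phi); uz = cz;
        if (roulette_threshold > 0 && w < roulette_threshold) {
          if (rng.runif() < roulette_survive) {
            w_roulette_net -= w * (1.0 / roulette_survive - 1.0);
            w /= roulette_survive;
          } else {
            w_roulette_net += w;
            break;
          }
        }
      } else {
        // reach a face
        x += ux * db; y += uy * db; z += uz * db; path += db;
        if (mua > 0) {
          double keep = std::exp(-mua * db);
          w_absorbed += w * (1.0 - keep);
          w *= keep;
        }
        if (path > path_max) { w_late += w; break; }
        double cosi = std::fabs(uz);
        double R = fresnel_R(n_sample, n_external, cosi);
        if (rng.runif() < R) {
          uz = -uz;  // specular internal reflection, stay inside
          z = (face == 1) ? thickness : 0.0;
        } else {
          // photon leaves the slab
          if (face == 1) {
            w_transmitted += w;
            double t = path / v;
            double r2 = x * x + y * y;
            if (r2 <= detector_radius * detector_radius && t >= t0) {
              int k = static_cast<int>((t - t0) / dt);
              if (k >= 0 && k < n_bins) {
                bins[k] += w;
                w_detected += w;
                ++n_detected;
              }
            }
          } else {
            w_reflected += w;
          }
          alive = false;
        }
      }
    }
  }

  double norm = static_cast<double>(N);
  for (int k = 0; k < n_bins; ++k) bins[k] /= norm;
  return List::create(
      _["values"] = bins,
      _["detected_weight"] = w_detected / norm,
      _["transmitted_weight"] = w_transmitted / norm,
      _["reflected_weight"] = w_reflected / norm,
      _["absorbed_weight"] = w_absorbed / norm,
      _["late_weight"] = w_late / norm,
      _["roulette_net_weight"] = w_roulette_net / norm,
      _["n_detected"] = static_cast<double>(n_detected));
}

// Direct (brute-force) discrete linear convolution, truncated to the length
// of the first argument. Skips negligible kernel entries for speed; with
// threshold = 0 it is the exact O(n*m) sum.
// [[Rcpp::export(name = ".conv_direct_cpp")]]
NumericVector conv_direct_cpp(NumericVector x, NumericVector kernel,
                              double rel_threshold = 0.0) {
  int n = x.size(), m = kernel.size();
  NumericVector out(n);
  double kmax = 0;
  for (int j = 0; j < m; ++j) kmax = std::max(kmax, std::fabs(kernel[j]));
  double thr = rel_threshold * kmax;
  for (int j = 0; j < m; ++j) {
    double kj = kernel[j];
    if (std::fabs(kj) <= thr && thr > 0) continue;
    if (kj == 0) continue;
    int top = n - j;
    for (int i = 0; i < top; ++i) out[i + j] += x[i] * kj;
  }
  return out;
}
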