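// Voxel-based Monte Carlo photon transport (mcxyz-style hop/drop/spin).
//
// Photons are launched collimated (+z) uniformly over the top face of the
// voxel grid, stepped through voxels with proper boundary-crossing
// bookkeeping of the dimensionless free path, deposit W * mu_a / mu_t at
// each interaction site, and scatter by the Henyey-Greenstein phase
// function with the local anisotropy. Lateral/bottom/top grid boundaries
// are absorbing (escaping weight is tallied by face). Background voxels
// (label 0) are vacuum: photons traverse them in a straight line.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding; one independent substream per photon.
struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0xD1B54A32D192ED03ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in (0, 1]; never 0 so -log() is finite
  double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
};

inline double hg_cos(double g, double u) {
  if (g < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

}  // namespace

// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport(IntegerVector labels, IntegerVector dims, double pitch,
                  NumericVector mua, NumericVector mus, NumericVector gg,
                  double n_photons, double seed,
                  double roulette_threshold = 1e-4,
                  double roulette_survival = 0.1) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double Lx = nx * pitch, Ly = ny * pitch, Lz = nz * pitch;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector dep(nvox);
  const double eps = pitch * 1e-9;
  const int nlab = mua.size();

  double esc_top_scat = 0.0, esc_top_unscat = 0.0, esc_other = 0.0;
  double absorbed = 0.0, roulette_net = 0.0;

  const long np = (long)n_photons;
  Rng rng;
  for (long ph = 0; ph < np; ++ph) {
    rng.seed((uint64_t)seed, (uint64_t)ph);
    double x = rng.unif() * Lx, y = rng.unif() * Ly, z = eps;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double W = 1.0;
    long nscat = 0;
    double sleft = -std::log(rng.unif());
    bool alive = true;

    while (alive) {
      // escape through a grid face?
      if (x < 0.0 || x >= Lx || y < 0.0 || y >= Ly || z >= Lz) {
        esc_other += W; break;
      }
      if (z < 0.0) {
        if (nscat > 0) esc_top_scat += W; else esc_top_unscat += W;
        break;
      }
      int ix = (int)(x / pitch), iy = (int)(y / pitch), iz = (int)(z / pitch);
      if (ix >= nx) ix = nx - 1;
      if (iy >= ny) iy = ny - 1;
      if (iz >= nz) iz = nz - 1;
      R_xlen_t vid = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      int lab = labels[vid];
      if (lab < 0 || lab >= nlab) stop("voxel label without assigned properties");
      double ma = mua[lab], ms = mus[lab];
      double mt = ma + ms;

      // distance to the voxel boundary along the current direction
      double db = 1e30;
      if (ux > 0)      db = std::min(db, ((ix + 1) * pitch - x) / ux);
      else if (ux < 0) db = std::min(db, (ix * pitch - x) / ux);
      if (uy > 0)      db = std::min(db, ((iy + 1) * pitch - y) / uy);
      else if (uy < 0) db = std::min(db, (iy * pitch - y) / uy);
      if (uz > 0)      db = std::min(db, ((iz + 1) * pitch - z) / uz);
      else if (uz < 0) db = std::min(db, (iz * pitch - z) / uz);
      if (db < 0) db = 0;

      if (mt <= 0.0) {  // vacuum: free flight to the next voxel
        double step = db + eps;
        x += ux * step; y += uy * step; z += uz * step;
        continue;
      }
      double ds = sleft / mt;
      if (ds > db) {  // cross into the next voxel, consume optical path
        double step = db + eps;
        x += ux * step; y += uy * step; z += uz * step;
        sleft -= (db + eps) * mt;
        if (sleft < 0) sleft = 0;
        continue;
      }
      // interaction inside this voxel
      x += ux * ds; y += uy * ds; z += uz * ds;
      double dw = W * ma / mt;
      dep[vid] += dw;
      absorbed += dw;
      W -= dw;
      ++nscat;
      // spin: HG deflection + uniform azimuth
      double ct = hg_cos(gg[lab], rng.unif());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * rng.unif();
      double cp = std::cos(phi), sp = std::sin(phi);
      double nux, nuy, nuz;
      if (std::fabs(uz) > 0.99999) {
        nux = st * cp;
        nuy = st * sp;
        nuz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        nuz = -den * st * cp + uz * ct;
      }
      double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
      ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
      sleft = -std::log(rng.unif());
      // Russian roulette
      if (W < roulette_threshold) {
        if (rng.unif() <= roulette_survival) {
          double gain = W / roulette_survival - W;
          roulette_net -= gain;  // weight created
          W /= roulette_survival;
        } else {
          roulette_net += W;  // weight destroyed
          alive = false;
        }
      }
    }
  }

  return List::create(
    _["deposited"] = dep,
    _["absorbed"] = absorbed,
    _["escaped_top_scattered"] = esc_top_scat,
    _["escaped_top_unscattered"] = esc_top_unscat,
    _["escaped_other"] = esc_other,
    _["roulette_net"] = roulette_net,
    _["n_photons"] = (double)np);
}
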