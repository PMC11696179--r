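// Overdamped Langevin kernel for the reduced oligomer-DNA system.
//
// Beads live in a cubic periodic box. Interactions:
//   - harmonic bonds (DNA backbone and intra-complex links), per-bond rest
//     length and spring constant (stiff DNA backbone, soft floppy
//     intra-complex tethers);
//   - cosine bending potential on consecutive DNA triplets,
//     U = kAngle (1 + cos theta), harmonic in the bend angle near the
//     straight configuration and giving the double helix its persistence
//     length (kAngle * bond length ~ 50-70 nm);
//   - soft repulsion between binding units within repRange (enforces one
//     unit per motif well);
//   - short-range attractive well between binding units and motif beads:
//     U(r) = -eps * (1 - (r/rc)^2)^2 for r < rc, 0 beyond.
// Energies are in kT at the reference temperature; the update is
//   dx = F * dt + sqrt(2 * T * dt) * eta
// with unit mobility. Noise comes from R's RNG so a set.seed() on the R
// side makes trajectories bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double minImage(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// Fast Gaussian noise: xoshiro256++ + Box-Muller, seeded from R's RNG so a
// set.seed() on the R side still fixes the trajectory. norm_rand() itself is
// too slow for ~1e8 draws per run.
struct FastNormal {
  uint64_t s[4];
  double spare;
  bool hasSpare;
  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit FastNormal(uint64_t seed) : hasSpare(false) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t nextU64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double nextUnif() {               // in (0, 1)
    return ((nextU64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double nextNorm() {               // Marsaglia polar method
    if (hasSpare) { hasSpare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * nextUnif() - 1.0;
      v = 2.0 * nextUnif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    hasSpare = true;
    return u * f;
  }
};

// [[Rcpp::export(name = ".cgLangevinRun")]]
List cgLangevinRun(NumericMatrix pos0, double boxL,
                   IntegerMatrix bonds, NumericVector bondRest, NumericVector bondK,
                   IntegerMatrix triplets, double kAngle,
                   IntegerVector unitIdx, IntegerVector motifIdx,
                   double repRange, double kRep,
                   double eps, double rc,
                   int nSteps, double dt, int stride, double temperature) {
  const int n = pos0.nrow();
  const int nBonds = bonds.nrow();
  const int nTrip = triplets.nrow();
  const int nU = unitIdx.size();
  const int nM = motifIdx.size();
  if (nSteps <= 0 || stride <= 0) stop("nSteps and stride must be positive");

  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  std::vector<double> fx(n), fy(n), fz(n);

  const int nFrames = nSteps / stride;
  NumericVector traj(Dimension(n, 3, nFrames));
  const double noiseAmp = std::sqrt(2.0 * temperature * dt);
  const double rc2 = rc * rc;
  const double rep2 = repRange * repRange;

  uint64_t seed64;
  {
    RNGScope scope;   // derive the kernel seed from R's RNG stream
    seed64 = (uint64_t)(unif_rand() * 4294967296.0) << 32;
    seed64 |= (uint64_t)(unif_rand() * 4294967296.0);
  }
  FastNormal rng(seed64);
  int frame = 0;
  for (int step = 1; step <= nSteps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // harmonic bonds
    for (int b = 0; b < nBonds; ++b) {
      const int i = bonds(b, 0), j = bonds(b, 1);
      double dxv = minImage(x[i] - x[j], boxL);
      double dyv = minImage(y[i] - y[j], boxL);
      double dzv = minImage(z[i] - z[j], boxL);
      double r = std::sqrt(dxv * dxv + dyv * dyv + dzv * dzv);
      if (r < 1e-9) continue;
      double fmag = -bondK[b] * (r - bondRest[b]) / r;
      fx[i] += fmag * dxv; fy[i] += fmag * dyv; fz[i] += fmag * dzv;
      fx[j] -= fmag * dxv; fy[j] -= fmag * dyv; fz[j] -= fmag * dzv;
    }

    // DNA bending stiffness
    if (kAngle > 0.0) {
      for (int t = 0; t < nTrip; ++t) {
        const int a = triplets(t, 0), b = triplets(t, 1), c = triplets(t, 2);
        double ux = minImage(x[a] - x[b], boxL);
        double uy = minImage(y[a] - y[b], boxL);
        double uz = minImage(z[a] - z[b], boxL);
        double vx = minImage(x[c] - x[b], boxL);
        double vy = minImage(y[c] - y[b], boxL);
        double vz = minImage(z[c] - z[b], boxL);
        double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
        double lv = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (lu < 1e-9 || lv < 1e-9) continue;
        double ct = (ux * vx + uy * vy + uz * vz) / (lu * lv);
        if (ct > 1.0) ct = 1.0;
        if (ct < -1.0) ct = -1.0;
        // F = -kAngle * d(cos theta)/dr  (no trig calls, no singularity)
        double uhx = ux / lu, uhy = uy / lu, uhz = uz / lu;
        double vhx = vx / lv, vhy = vy / lv, vhz = vz / lv;
        double fax = -kAngle / lu * (vhx - ct * uhx);
        double fay = -kAngle / lu * (vhy - ct * uhy);
        double faz = -kAngle / lu * (vhz - ct * uhz);
        double fcx = -kAngle / lv * (uhx - ct * vhx);
        double fcy = -kAngle / lv * (uhy - ct * vhy);
        double fcz = -kAngle / lv * (uhz - ct * vhz);
        fx[a] += fax; fy[a] += fay; fz[a] += faz;
        fx[c] += fcx; fy[c] += fcy; fz[c] += fcz;
        fx[b] -= fax + fcx; fy[b] -= fay + fcy; fz[b] -= faz + fcz;
      }
    }

    // unit-unit soft repulsion
    for (int a = 0; a < nU; ++a) {
      const int i = unitIdx[a];
      for (int b = a + 1; b < nU; ++b) {
        const int j = unitIdx[b];
        double dxv = minImage(x[i] - x[j], boxL);
        if (std::fabs(dxv) > repRange) continue;
        double dyv = minImage(y[i] - y[j], boxL);
        if (std::fabs(dyv) > repRange) continue;
        double dzv = minImage(z[i] - z[j], boxL);
        double r2 = dxv * dxv + dyv * dyv + dzv * dzv;
        if (r2 >= rep2 || r2 < 1e-18) continue;
        double r = std::sqrt(r2);
        double fmag = kRep * (repRange - r) / r;  // repulsive
        fx[i] += fmag * dxv; fy[i] += fmag * dyv; fz[i] += fmag * dzv;
        fx[j] -= fmag * dxv; fy[j] -= fmag * dyv; fz[j] -= fmag * dzv;
      }
    }

    // unit-motif attraction
    if (eps > 0.0) {
      for (int a = 0; a < nU; ++a) {
        const int i = unitIdx[a];
        for (int m = 0; m < nM; ++m) {
          const int j = motifIdx[m];
          double dxv = minImage(x[i] - x[j], boxL);
          if (std::fabs(dxv) > rc) continue;
          double dyv = minImage(y[i] - y[j], boxL);
          if (std::fabs(dyv) > rc) continue;
          double dzv = minImage(z[i] - z[j], boxL);
          double r2 = dxv * dxv + dyv * dyv + dzv * dzv;
          if (r2 >= rc2 || r2 < 1e-18) continue;
          double u2 = r2 / rc2;
          // dU/dr = 4 eps (r/rc^2) (1 - u2); force = -dU/dr toward the bead
          double fOverR = -4.0 * eps * (1.0 - u2) / rc2;
          fx[i] += fOverR * dxv; fy[i] += fOverR * dyv; fz[i] += fOverR * dzv;
          fx[j] -= fOverR * dxv; fy[j] -= fOverR * dyv; fz[j] -= fOverR * dzv;
        }
      }
    }

    // overdamped update + wrap
    for (int i = 0; i < n; ++i) {
      x[i] += fx[i] * dt + noiseAmp * rng.nextNorm();
      y[i] += fy[i] * dt + noiseAmp * rng.nextNorm();
      z[i] += fz[i] * dt + noiseAmp * rng.nextNorm();
      x[i] -= boxL * std::floor(x[i] / boxL);
      y[i] -= boxL * std::floor(y[i] / boxL);
      z[i] -= boxL * std::floor(z[i] / boxL);
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(z[i])) {
        stop("non-finite coordinate at step %d", step);
      }
    }

    if (step % stride == 0 && frame < nFrames) {
      for (int i = 0; i < n; ++i) {
        traj[frame * 3 * n + 0 * n + i] = x[i];
        traj[frame * 3 * n + 1 * n + i] = y[i];
        traj[frame * 3 * n + 2 * n + i] = z[i];
      }
      ++frame;
    }
  }

  NumericMatrix finalPos(n, 3);
  for (int i = 0; i < n; ++i) {
    finalPos(i, 0) = x[i]; finalPos(i, 1) = y[i]; finalPos(i, 2) = z[i];
  }
  return List::create(_["frames"] = traj, _["finalPositions"] = finalPos);
}
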