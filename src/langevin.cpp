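// Overdamped Langevin dynamics on the 1-D folding landscape.
//
// Random numbers: one counter-based generator per trajectory/replicate,
// seeded from (master seed, replicate index) through splitmix64 into
// xoshiro256**, with Marsaglia's polar method for normals. Replicate sets
// are therefore reproducible and order-independent.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
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
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {  // polar (Marsaglia) method
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

inline uint64_t combine_seed(int master, int replicate) {
  return (static_cast<uint64_t>(static_cast<uint32_t>(master)) << 32) ^
         static_cast<uint64_t>(static_cast<uint32_t>(replicate));
}

// Potential types: 0 flat, 1 harmonic (params: kappa),
// 2 landscape (params: U0, a, G, z0, s, lP, dLC, kT, morse_squared).
// Returns dU/dz at force F (the tilt -F z is applied here).
inline double grad(int type, const double* p, double z, double F) {
  switch (type) {
  case 0: return -F;
  case 1: return p[0] * z - F;
  default: {
    const double U0 = p[0], a = p[1], G = p[2], z0 = p[3], s = p[4];
    const double lP = p[5], dLC = p[6], kT = p[7];
    const double e = std::exp(-a * z);
    const double dm = (p[8] != 0.0) ? 2.0 * U0 * a * e * (1.0 - e)
                                    : U0 * a * e;
    const double dz = z - z0;
    const double dg = -2.0 * G * dz / s * std::exp(-dz * dz / s);
    const double x = z / dLC;
    const double om = 1.0 - x;
    const double fw = (kT / lP) * (0.25 / (om * om) + x - 0.25);
    return dm + dg + fw - F;
  }
  }
}

inline double protocol_force(int mode, const double* pp,
                             const double* st, const double* sf,
                             int ns, double t) {
  switch (mode) {
  case 0: return pp[0];                       // constant F0
  case 1: return pp[0] + pp[2] * t;           // ramp F0 + a t
  case 2: return (t < pp[3]) ? pp[0] : pp[1]; // jump F0 -> F1 at jump_time
  default: {                                  // piecewise-linear schedule
    if (t <= st[0]) return sf[0];
    if (t >= st[ns - 1]) return sf[ns - 1];
    int lo = 0, hi = ns - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2;
      if (st[mid] <= t) lo = mid; else hi = mid; }
    const double w = (t - st[lo]) / (st[hi] - st[lo]);
    return sf[lo] + w * (sf[hi] - sf[lo]);
  }
  }
}


// Linear-interpolation table of the zero-force gradient dU0/dz on
// [zlo, zhi]: the applied force enters the drift linearly, so one table
// serves constant, ramp, jump and scheduled protocols alike. Interpolation
// error is negligible at the table resolution used (2^14 nodes).
struct GradTable {
  double zlo, inv_h;
  std::vector<double> g;
  void build(int type, const double* p, double lo, double hi, int n = 16384) {
    zlo = lo;
    const double h = (hi - lo) / (n - 1);
    inv_h = 1.0 / h;
    g.resize(n);
    for (int i = 0; i < n; ++i) g[i] = grad(type, p, lo + i * h, 0.0);
  }
  inline double operator()(double z) const {
    double x = (z - zlo) * inv_h;
    if (x < 0.0) x = 0.0;
    const int n = static_cast<int>(g.size());
    if (x >= n - 1) x = n - 1.000001;
    const int i = static_cast<int>(x);
    const double w = x - i;
    return g[i] + w * (g[i + 1] - g[i]);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_langevin(int pot_type, NumericVector pot_params,
                  double z_init, double dt, double nsteps_d, int decim,
                  double D, double kT,
                  int proto_mode, NumericVector proto_params,
                  NumericVector sched_t, NumericVector sched_F,
                  double zlo, double zhi,
                  int seed_master, int seed_replicate) {
  const double mob = D / kT;
  const double noise = std::sqrt(2.0 * D * dt);
  const double* pp = pot_params.begin();
  const double* prp = proto_params.begin();
  const double* st = sched_t.size() ? sched_t.begin() : nullptr;
  const double* sf = sched_F.size() ? sched_F.begin() : nullptr;
  const int ns = sched_t.size();
  Xoshiro rng(combine_seed(seed_master, seed_replicate));
  GradTable tab;
  tab.build(pot_type, pp, zlo, zhi);

  const long long nsteps = static_cast<long long>(nsteps_d);
  const long long nsamp = nsteps / decim;
  NumericVector out_z(nsamp), out_F(nsamp), out_t(nsamp);

  double z = z_init;
  long long k = 0;
  for (long long i = 1; i <= nsteps; ++i) {
    const double t = (i - 1) * dt;
    const double F = protocol_force(proto_mode, prp, st, sf, ns, t);
    z += -mob * (tab(z) - F) * dt + noise * rng.norm();
    if (z < zlo) z = 2.0 * zlo - z;
    if (z > zhi) z = 2.0 * zhi - z;
    if (!std::isfinite(z) || z < zlo || z > zhi)
      stop("Langevin run aborted at step %lld: position not finite/in-domain",
           i);
    if (i % decim == 0) {
      out_t[k] = i * dt;
      out_z[k] = z;
      out_F[k] = protocol_force(proto_mode, prp, st, sf, ns, i * dt);
      ++k;
    }
  }
  return List::create(_["time"] = out_t, _["force"] = out_F,
                      _["extension"] = out_z);
}

// [[Rcpp::export]]
NumericVector cpp_first_passage(int pot_type, NumericVector pot_params,
                                double force, double start, double absorb,
                                double reflect, double dt, double D, double kT,
                                int n, int seed_master, int seed_base,
                                double max_steps) {
  const double mob = D / kT;
  const double noise = std::sqrt(2.0 * D * dt);
  const double* pp = pot_params.begin();
  const bool rightward = absorb > start;
  NumericVector times(n);
  const double lo = std::min(reflect, absorb), hi = std::max(reflect, absorb);
  GradTable tab;
  tab.build(pot_type, pp, lo, hi);
  const double drift_scale = -mob * dt;

  for (int r = 0; r < n; ++r) {
    Xoshiro rng(combine_seed(seed_master, seed_base + r));
    double z = start;
    long long i = 0;
    const long long mx = static_cast<long long>(max_steps);
    for (;;) {
      ++i;
      if (i > mx)
        stop("first-passage run %d exceeded max_steps", r + 1);
      z += drift_scale * (tab(z) - force) + noise * rng.norm();
      if (!std::isfinite(z))
        stop("first-passage run %d aborted at step %lld: non-finite position",
             r + 1, i);
      if (rightward) {
        if (z < reflect) z = 2.0 * reflect - z;
        if (z >= absorb) break;
      } else {
        if (z > reflect) z = 2.0 * reflect - z;
        if (z <= absorb) break;
      }
    }
    times[r] = i * dt;
  }
  return times;
}

// Dual-threshold (Schmitt trigger) state labelling: 1 = folded (low),
// 2 = unfolded (high). Samples inside the band keep the previous label;
// the initial label comes from the nearer threshold.
// [[Rcpp::export]]
IntegerVector cpp_schmitt(NumericVector x, double low, double high) {
  const int n = x.size();
  IntegerVector state(n);
  int cur;
  if (x[0] >= high) cur = 2;
  else if (x[0] <= low) cur = 1;
  else cur = (x[0] - low < high - x[0]) ? 1 : 2;
  for (int i = 0; i < n; ++i) {
    if (x[i] >= high) cur = 2;
    else if (x[i] <= low) cur = 1;
    state[i] = cur;
  }
  return state;
}

// Rupture-force sampler for a linear force ramp with the Bell rate law,
// by Ogata thinning over 1-pN force windows (dominating rate = window-top
// rate, since the Bell rate is increasing for x_dagger > 0).
// [[Rcpp::export]]
NumericVector cpp_sample_ramp(int n, double k0, double x_dagger, double a,
                              double kT, int seed, double f_cap) {
  NumericVector out(n);
  const double beta = x_dagger / kT;
  for (int r = 0; r < n; ++r) {
    Xoshiro rng(combine_seed(seed, r));
    double F = 0.0;
    bool done = false;
    while (!done) {
      const double Ftop = std::min(F + 1.0, f_cap);
      const double rmax = k0 * std::exp(beta * Ftop);
      double Fc = F;
      for (;;) {
        // candidate gap in force units: hazard rmax per unit time = rmax/a
        Fc += -std::log(rng.unif()) * a / rmax;
        if (Fc >= Ftop) break;
        if (rng.unif() < k0 * std::exp(beta * Fc) / rmax) {
          out[r] = Fc; done = true; break;
        }
      }
      if (!done) {
        F = Ftop;
        if (F >= f_cap) { out[r] = f_cap; done = true; }
      }
    }
  }
  return out;
}
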