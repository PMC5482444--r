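#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic PCG32 stream for attractant-field noise.
//
// Field realizations must be bit-identical when regenerated from the same
// integer seed (paired wild-type/mutant fitness evaluation re-uses them),
// while agent-level randomness flows from R's global RNG. Each field
// therefore owns a private PCG32 generator keyed by its seed.
// ---------------------------------------------------------------------------

struct Pcg32 {
  uint64_t state;
  static const uint64_t inc = 0xda3e39cb94b95bdbULL; // fixed odd increment
  explicit Pcg32(uint64_t seed) {
    state = 0u;
    next();
    state += seed + 0x853c49e6748fea9bULL;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  // Box-Muller, stateless (no spare caching) so the stream is a pure
  // function of the draw count.
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

// [[Rcpp::export]]
NumericVector cpp_pcg_normals(double seed, int n) {
  Pcg32 rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.norm();
  return out;
}

// 1D spectral field: c(x,t) = max(0, sum_p X_p cos(2*pi*p*x/ell) +
//                                        Y_p sin(2*pi*p*x/ell))
// Weights follow the AR(1) update X <- X(1 - dtc/T) + eta*sqrt(2*dtc/(T*p*)).
// Draw order per update: X_1..X_pstar then Y_1..Y_pstar.

struct Field1D {
  int p_star;
  double ell, T, dtc, a, sd;
  std::vector<double> X, Y;
  Pcg32 rng;
  Field1D(int p_star_, double ell_, double T_, double dtc_, uint64_t seed)
    : p_star(p_star_), ell(ell_), T(T_), dtc(dtc_),
      a(1.0 - dtc_ / T_), sd(std::sqrt(2.0 * dtc_ / (T_ * p_star_))),
      X(p_star_, 0.0), Y(p_star_, 0.0), rng(seed) {}
  void update() {
    for (int p = 0; p < p_star; ++p) X[p] = a * X[p] + sd * rng.norm();
    for (int p = 0; p < p_star; ++p) Y[p] = a * Y[p] + sd * rng.norm();
  }
  void equilibrate(int n_eq) { for (int i = 0; i < n_eq; ++i) update(); }
  double conc(double x) const {
    double w = 6.283185307179586 * x / ell;
    double c1 = std::cos(w), s1 = std::sin(w);
    double cp = c1, sp = s1, sum = 0.0;
    for (int p = 0; p < p_star; ++p) {
      sum += X[p] * cp + Y[p] * sp;
      double cn = cp * c1 - sp * s1;
      sp = cp * s1 + sp * c1;
      cp = cn;
    }
    return sum > 0.0 ? sum : 0.0;
  }
};

// [[Rcpp::export]]
List cpp_field_series(double T, double dtc, int p_star, double seed,
                      int n_eq, int n_keep) {
  // Returns the weight trajectory after equilibration: (n_keep x 2*p_star)
  // matrix, rows are successive updates, columns X_1..X_p*, Y_1..Y_p*.
  Field1D f(p_star, 100.0, T, dtc, (uint64_t)seed);
  f.equilibrate(n_eq);
  NumericMatrix out(n_keep, 2 * p_star);
  for (int i = 0; i < n_keep; ++i) {
    f.update();
    for (int p = 0; p < p_star; ++p) {
      out(i, p) = f.X[p];
      out(i, p_star + p) = f.Y[p];
    }
  }
  return List::create(_["weights"] = out,
                      _["X"] = NumericVector(f.X.begin(), f.X.end()),
                      _["Y"] = NumericVector(f.Y.begin(), f.Y.end()));
}

// [[Rcpp::export]]
List cpp_field_snapshot(double T, double dtc, int p_star, double seed,
                        int n_eq) {
  Field1D f(p_star, 100.0, T, dtc, (uint64_t)seed);
  f.equilibrate(n_eq);
  return List::create(_["X"] = NumericVector(f.X.begin(), f.X.end()),
                      _["Y"] = NumericVector(f.Y.begin(), f.Y.end()));
}

// [[Rcpp::export]]
NumericVector cpp_conc1d(NumericVector X, NumericVector Y, double ell,
                         NumericVector x, bool clip = true) {
  int p_star = X.size(), n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double w = 6.283185307179586 * x[i] / ell;
    double c1 = std::cos(w), s1 = std::sin(w);
    double cp = c1, sp = s1, sum = 0.0;
    for (int p = 0; p < p_star; ++p) {
      sum += X[p] * cp + Y[p] * sp;
      double cn = cp * c1 - sp * s1;
      sp = cp * s1 + sp * c1;
      cp = cn;
    }
    out[i] = (clip && sum < 0.0) ? 0.0 : sum;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conc3d(NumericVector X3, NumericVector Y3, int p_star,
                         double ell, NumericVector x, NumericVector y,
                         NumericVector z, bool clip = false) {
  // mode index: ((p-1)*p_star + (q-1))*p_star + (r-1), p,q,r in 1..p_star
  int n = x.size();
  NumericVector out(n);
  double w = 6.283185307179586 / ell;
  for (int i = 0; i < n; ++i) {
    double sum = 0.0;
    int k = 0;
    for (int p = 1; p <= p_star; ++p)
      for (int q = 1; q <= p_star; ++q)
        for (int r = 1; r <= p_star; ++r, ++k) {
          double ph = w * (p * x[i] + q * y[i] + r * z[i]);
          sum += X3[k] * std::cos(ph) + Y3[k] * std::sin(ph);
        }
    out[i] = (clip && sum < 0.0) ? 0.0 : sum;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Agent simulation.
//
// Environment codes: 0 = stochastic 1D field, 1 = constant, 2 = step,
// 3 = two-Gaussian oscillating world. Modes: 0 = run right, 1 = run left,
// 2 = tumble.
// ---------------------------------------------------------------------------

static inline double wrap_mod(double x, double m) {
  // x mod m in [0, m); avoids std::fmod (keeps the binary portable across
  // glibc symbol versions)
  return x - m * std::floor(x / m);
}

static inline double env_two_gauss(double x, double t, const double *ep) {
  // ep: period, mu1, mu2, sigma, ell
  double P = ep[0], mu1 = ep[1], mu2 = ep[2], sg = ep[3], ell = ep[4];
  double A1 = 0.5 * (1.0 + std::cos(6.283185307179586 * t / P));
  double d1 = wrap_mod(x - mu1 + 1.5 * ell, ell) - 0.5 * ell;
  double d2 = wrap_mod(x - mu2 + 1.5 * ell, ell) - 0.5 * ell;
  return A1 * std::exp(-0.5 * d1 * d1 / (sg * sg)) +
         (1.0 - A1) * std::exp(-0.5 * d2 * d2 / (sg * sg));
}

// rp: alpha0, beta, A, B, tau
// cfg: v, dt_B, stop_attractant, t_max, ell
// field_par: T, dtc, p_star, seed, n_eq (stochastic env only)
// [[Rcpp::export]]
List cpp_simulate(NumericVector rp, int env_type, NumericVector env_par,
                  NumericVector cfg, NumericVector field_par,
                  double record_every = 0.0) {
  double alpha0 = rp[0], beta = rp[1], A = rp[2], B = rp[3], tau = rp[4];
  double v = cfg[0], dtB = cfg[1], stop = cfg[2], tmax = cfg[3], ell = cfg[4];

  Field1D *fld = nullptr;
  double dtc = 0.0, next_ft = 0.0;
  if (env_type == 0) {
    dtc = field_par[1];
    fld = new Field1D((int)field_par[2], ell, field_par[0], dtc,
                      (uint64_t)field_par[3]);
    fld->equilibrate((int)field_par[4]);
    next_ft = dtc;
  }

  // initial agent state: uniform position, running, random direction
  double x = R::unif_rand() * ell;
  int mode = (R::unif_rand() < 0.5) ? 0 : 1;

  double tau2 = tau * tau;
  double e = std::exp(-dtB / tau);
  double Ao = A / tau, Bo = B / tau2;
  double p_stop = -std::expm1(-beta * dtB);

  // memory initialized at the local equilibrated concentration
  double c_here;
  switch (env_type) {
    case 0: c_here = fld->conc(x); break;
    case 1: c_here = env_par[0]; break;
    case 2: c_here = (0.0 >= env_par[1] && 0.0 < env_par[2]) ? env_par[0] : 0.0;
            break;
    default: c_here = env_two_gauss(x, 0.0, env_par.begin());
  }
  double M1 = c_here * tau, M2 = c_here * tau2;

  double t = 0.0, acc = 0.0;
  bool truncated = false;

  bool record = record_every > 0.0;
  int rec_stride = record ? std::max(1, (int)std::lround(record_every / dtB)) : 0;
  std::vector<double> traj; // rows of (t, x, mode, c, alpha, acc)
  long step = 0;

  // A tumbling agent holds position and exits with constant per-step
  // probability p_stop, independent of alpha; on the non-recording path the
  // tumble dwell is therefore sampled geometrically and the memory /
  // accumulation advanced in bulk over constant-concentration segments
  // (exact: the exponential-filter update composes over any step count).
  bool fast_tumble = !record;

  while (true) {
    if (acc >= stop) break;
    if (t >= tmax) { truncated = true; break; }
    if (env_type == 0) {
      while (next_ft <= t + 1e-12) { fld->update(); next_ft += dtc; }
    }

    if (fast_tumble && mode == 2 && env_type <= 1) {
      // steps the agent stays tumbling before the exit attempt succeeds
      double u = R::unif_rand();
      long k;
      if (p_stop >= 1.0) k = 0;
      else if (p_stop <= 1e-14) k = (long)4e15;
      else {
        double kd = std::floor(std::log(u) / std::log(1.0 - p_stop));
        k = (kd > 4e15) ? (long)4e15 : (long)kd;
      }
      while (k > 0) {
        // constant-c segment: until the next field update, the threshold
        // crossing, or the time cap, whichever is nearest
        double c = (env_type == 0) ? fld->conc(x) : env_par[0];
        long n_seg = k;
        if (env_type == 0) {
          long n_field = (long)std::ceil((next_ft - t) / dtB - 1e-9);
          if (n_field < 1) n_field = 1;
          if (n_field < n_seg) n_seg = n_field;
        }
        if (c > 0.0) {
          long n_cross = (long)std::ceil((stop - acc) / (c * dtB) - 1e-9);
          if (n_cross < n_seg) n_seg = n_cross;
        }
        long n_cap = (long)std::ceil((tmax - t) / dtB - 1e-9);
        if (n_cap < n_seg) n_seg = n_cap;
        if (n_seg < 1) n_seg = 1; // guarantee progress at rounding edges
        double dt_seg = n_seg * dtB;
        double e_seg = std::exp(-dt_seg / tau);
        double M1old = M1;
        M1 = e_seg * M1 + c * tau * (1.0 - e_seg);
        M2 = e_seg * (M2 + dt_seg * M1old) +
          c * (tau2 - e_seg * (tau2 + tau * dt_seg));
        acc += c * dt_seg;
        t += dt_seg;
        k -= n_seg;
        if (acc >= stop || t >= tmax - 1e-12) break;
        if (env_type == 0) {
          while (next_ft <= t + 1e-12) { fld->update(); next_ft += dtc; }
        }
      }
      if (acc >= stop) break;
      if (t >= tmax) { truncated = true; break; }
      // the exit step itself falls through to the ordinary per-step code,
      // with the success of the exit attempt already decided
      double c = (env_type == 0) ? fld->conc(x) : env_par[0];
      double M1old = M1;
      M1 = e * M1 + c * tau * (1.0 - e);
      M2 = e * (M2 + dtB * M1old) + c * (tau2 - e * (tau2 + tau * dtB));
      mode = (R::unif_rand() < 0.5) ? 0 : 1;
      x += (mode == 0 ? v : -v) * dtB;
      if (x >= ell || x < 0.0) x = wrap_mod(x, ell);
      acc += c * dtB;
      t += dtB;
      ++step;
      continue;
    }

    double c;
    switch (env_type) {
      case 0: c = fld->conc(x); break;
      case 1: c = env_par[0]; break;
      case 2: c = (t >= env_par[1] && t < env_par[2]) ? env_par[0] : 0.0; break;
      default: c = env_two_gauss(x, t, env_par.begin());
    }
    // exact exponential-filter memory update (c constant over the step)
    double M1old = M1;
    M1 = e * M1 + c * tau * (1.0 - e);
    M2 = e * (M2 + dtB * M1old) + c * (tau2 - e * (tau2 + tau * dtB));
    double alpha = alpha0 + Ao * M1 + Bo * M2;
    if (alpha < 0.0) alpha = 0.0;
    // one switch attempt per step, resolved before movement
    if (mode == 2) {
      if (R::unif_rand() < p_stop)
        mode = (R::unif_rand() < 0.5) ? 0 : 1;
    } else if (alpha > 0.0) {
      double p_start = -std::expm1(-alpha * dtB);
      if (R::unif_rand() < p_start) mode = 2;
    }
    if (mode != 2) {
      x += (mode == 0 ? v : -v) * dtB;
      if (x >= ell || x < 0.0) x = wrap_mod(x, ell);
    }
    acc += c * dtB;
    t += dtB;
    ++step;
    if (record && (step % rec_stride == 0)) {
      traj.push_back(t); traj.push_back(x); traj.push_back((double)mode);
      traj.push_back(c); traj.push_back(alpha); traj.push_back(acc);
    }
  }

  if (fld) delete fld;

  List out = List::create(_["D"] = t, _["truncated"] = truncated,
                          _["accumulated"] = acc);
  if (record) {
    int nrow = traj.size() / 6;
    NumericMatrix m(nrow, 6);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < 6; ++j) m(i, j) = traj[6 * i + j];
    out["trajectory"] = m;
  }
  return out;
}
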