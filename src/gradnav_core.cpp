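#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based noise stream.
//
// Each draw is a pure function of (seed, index): splitmix64 finalizer over the
// index stream, Box-Muller for normals. This makes any simulation segment
// bit-identical on replay given (seed, start, n_frames), with no dependence on
// R's global RNG state.
// ---------------------------------------------------------------------------

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unif53(uint64_t seed, uint64_t idx) {
  // uniform in (0, 1): never exactly 0, safe under log()
  uint64_t z = mix64(seed ^ mix64(idx + 0x632BE59BD9B4E019ULL));
  return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double normal_draw(uint64_t seed, uint64_t k) {
  uint64_t j = k >> 1;
  double u1 = unif53(seed, 2 * j);
  double u2 = unif53(seed, 2 * j + 1);
  double r = std::sqrt(-2.0 * std::log(u1));
  double a = 2.0 * M_PI * u2;
  return (k & 1ULL) ? r * std::sin(a) : r * std::cos(a);
}

// [[Rcpp::export(name = ".noise_normal_cpp")]]
NumericVector noise_normal_cpp(double seed, double from, int n) {
  uint64_t s = (uint64_t) seed;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = normal_draw(s, (uint64_t)(from + i));
  return out;
}

// ---------------------------------------------------------------------------
// Gaussian-sum potential: V(X) = sum_j A_j exp(a_j dx^2 + b_j dx dy + c_j dy^2)
// terms: matrix with columns A, a, b, c, x0, y0
// ---------------------------------------------------------------------------

static inline double pes_v(const NumericMatrix& tm, double x, double y) {
  double v = 0.0;
  for (int j = 0; j < tm.nrow(); ++j) {
    double dx = x - tm(j, 4), dy = y - tm(j, 5);
    v += tm(j, 0) * std::exp(tm(j, 1) * dx * dx + tm(j, 2) * dx * dy + tm(j, 3) * dy * dy);
  }
  return v;
}

static inline void pes_g(const NumericMatrix& tm, double x, double y,
                         double& gx, double& gy) {
  gx = 0.0; gy = 0.0;
  for (int j = 0; j < tm.nrow(); ++j) {
    double dx = x - tm(j, 4), dy = y - tm(j, 5);
    double e = tm(j, 0) * std::exp(tm(j, 1) * dx * dx + tm(j, 2) * dx * dy + tm(j, 3) * dy * dy);
    gx += e * (2.0 * tm(j, 1) * dx + tm(j, 2) * dy);
    gy += e * (tm(j, 2) * dx + 2.0 * tm(j, 3) * dy);
  }
}

// [[Rcpp::export(name = ".pes_eval_cpp")]]
NumericVector pes_eval_cpp(NumericMatrix terms, NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pes_v(terms, pts(i, 0), pts(i, 1));
  return out;
}

// [[Rcpp::export(name = ".pes_grad_cpp")]]
NumericMatrix pes_grad_cpp(NumericMatrix terms, NumericMatrix pts) {
  int n = pts.nrow();
  NumericMatrix out(n, 2);
  double gx, gy;
  for (int i = 0; i < n; ++i) {
    pes_g(terms, pts(i, 0), pts(i, 1), gx, gy);
    out(i, 0) = gx; out(i, 1) = gy;
  }
  return out;
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator.
// Step (noise xi = two standard normals):
//   B: v += dt/2 * F(x)/m
//   A: x += dt/2 * v
//   O: v  = aa*v + sig*xi,  aa = exp(-gamma*dt), sig = sqrt(kBT/m (1-aa^2))
//   A: x += dt/2 * v
//   B: v += dt/2 * F(x)/m
// ---------------------------------------------------------------------------

static inline void baoab_step(const NumericMatrix& tm,
                              double dt, double m, double aa, double sig,
                              double& x, double& y, double& vx, double& vy,
                              double n1, double n2) {
  double gx, gy;
  pes_g(tm, x, y, gx, gy);
  vx += 0.5 * dt * (-gx) / m;
  vy += 0.5 * dt * (-gy) / m;
  x += 0.5 * dt * vx;
  y += 0.5 * dt * vy;
  vx = aa * vx + sig * n1;
  vy = aa * vy + sig * n2;
  x += 0.5 * dt * vx;
  y += 0.5 * dt * vy;
  pes_g(tm, x, y, gx, gy);
  vx += 0.5 * dt * (-gx) / m;
  vy += 0.5 * dt * (-gy) / m;
}

// [[Rcpp::export(name = ".ld_step_cpp")]]
List ld_step_cpp(NumericMatrix terms, NumericVector pos, NumericVector vel,
                 NumericVector noise, double dt, double friction, double mass,
                 double temperature, double kB) {
  double aa = std::exp(-friction * dt);
  double sig = std::sqrt(kB * temperature / mass * (1.0 - aa * aa));
  double x = pos[0], y = pos[1], vx = vel[0], vy = vel[1];
  baoab_step(terms, dt, mass, aa, sig, x, y, vx, vy, noise[0], noise[1]);
  return List::create(_["position"] = NumericVector::create(x, y),
                      _["velocity"] = NumericVector::create(vx, vy));
}

// [[Rcpp::export(name = ".ld_simulate_cpp")]]
List ld_simulate_cpp(NumericMatrix terms, NumericVector start, int n_frames,
                     double dt, double friction, double mass,
                     double temperature, double kB, double seed,
                     Nullable<NumericVector> v0, double sanity_box) {
  uint64_t s = (uint64_t) seed;
  double aa = std::exp(-friction * dt);
  double sig = std::sqrt(kB * temperature / mass * (1.0 - aa * aa));
  double x = start[0], y = start[1];
  double vx, vy;
  if (v0.isNotNull()) {
    NumericVector v(v0);
    vx = v[0]; vy = v[1];
  } else {
    // Maxwell-Boltzmann start drawn from the segment's own stream
    double vth = std::sqrt(kB * temperature / mass);
    vx = vth * normal_draw(s, 0);
    vy = vth * normal_draw(s, 1);
  }
  NumericMatrix out(n_frames, 2);
  out(0, 0) = x; out(0, 1) = y;
  for (int i = 1; i < n_frames; ++i) {
    double n1 = normal_draw(s, (uint64_t)(2 * i));
    double n2 = normal_draw(s, (uint64_t)(2 * i + 1));
    baoab_step(terms, dt, mass, aa, sig, x, y, vx, vy, n1, n2);
    if (!(std::fabs(x) <= sanity_box && std::fabs(y) <= sanity_box))
      stop("Langevin trajectory left the sanity box (|x| or |y| > %g) at frame %d; "
           "the time step is too large for this surface", sanity_box, i);
    out(i, 0) = x; out(i, 1) = y;
  }
  return List::create(_["points"] = out,
                      _["v_final"] = NumericVector::create(vx, vy));
}

// ---------------------------------------------------------------------------
// Basin assignment by damped gradient descent.
//
// Displacement per iteration is capped at `step` (position units); near a
// minimum the step degenerates to plain gradient descent with rate `alpha`,
// which converges for curvature < 2/alpha. A point is assigned once it comes
// within snap_radius of a known minimum, or when |grad| < tol and the nearest
// minimum is within assign_radius; otherwise NA. Starts with V above e_cap are
// NA (divergent region). Batch version memoizes on a 1e-3 grid.
// ---------------------------------------------------------------------------

static int descend_assign(const NumericMatrix& tm, const NumericMatrix& mins,
                          double x, double y, double step, double alpha,
                          double tol, int max_iter, double snap_radius,
                          double assign_radius, double e_cap) {
  if (pes_v(tm, x, y) > e_cap) return NA_INTEGER;
  int nm = mins.nrow();
  for (int it = 0; it < max_iter; ++it) {
    // snap to a minimum when close enough
    for (int j = 0; j < nm; ++j) {
      double dx = x - mins(j, 0), dy = y - mins(j, 1);
      if (dx * dx + dy * dy < snap_radius * snap_radius) return j + 1;
    }
    double gx, gy;
    pes_g(tm, x, y, gx, gy);
    double gn = std::sqrt(gx * gx + gy * gy);
    if (gn < tol) break;
    double sc = std::min(alpha, step / gn);
    x -= sc * gx;
    y -= sc * gy;
  }
  int best = NA_INTEGER;
  double bd = assign_radius * assign_radius;
  for (int j = 0; j < nm; ++j) {
    double dx = x - mins(j, 0), dy = y - mins(j, 1);
    double d2 = dx * dx + dy * dy;
    if (d2 < bd) { bd = d2; best = j + 1; }
  }
  return best;
}

// [[Rcpp::export(name = ".descend_cpp")]]
List descend_cpp(NumericMatrix terms, NumericVector p0, double step,
                 double alpha, double tol, int max_iter) {
  double x = p0[0], y = p0[1];
  bool conv = false;
  for (int it = 0; it < max_iter; ++it) {
    double gx, gy;
    pes_g(terms, x, y, gx, gy);
    double gn = std::sqrt(gx * gx + gy * gy);
    if (gn < tol) { conv = true; break; }
    double sc = std::min(alpha, step / gn);
    x -= sc * gx;
    y -= sc * gy;
  }
  return List::create(_["point"] = NumericVector::create(x, y),
                      _["converged"] = conv);
}

// [[Rcpp::export(name = ".assign_basins_cpp")]]
IntegerVector assign_basins_cpp(NumericMatrix terms, NumericMatrix pts,
                                NumericMatrix minima, double step, double alpha,
                                double tol, int max_iter, double snap_radius,
                                double assign_radius, double e_cap,
                                bool memoize) {
  int n = pts.nrow();
  IntegerVector out(n);
  std::unordered_map<int64_t, int> memo;
  const double res = 1e-3;
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    if (memoize) {
      int64_t kx = (int64_t) std::llround(x / res);
      int64_t ky = (int64_t) std::llround(y / res);
      int64_t key = kx * 4000037LL + ky;
      auto it = memo.find(key);
      if (it != memo.end()) { out[i] = it->second; continue; }
      double qx = kx * res, qy = ky * res;  // quantized start, < res/2 from x,y
      int b = descend_assign(terms, minima, qx, qy, step, alpha, tol, max_iter,
                             snap_radius, assign_radius, e_cap);
      memo[key] = b;
      out[i] = b;
    } else {
      out[i] = descend_assign(terms, minima, x, y, step, alpha, tol, max_iter,
                              snap_radius, assign_radius, e_cap);
    }
  }
  return out;
}
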