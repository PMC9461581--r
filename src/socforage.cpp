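// Core numerical engines: Euler-Maruyama bout simulator for coupled
// evidence-accumulation foragers, a 1D time-inhomogeneous Fokker-Planck
// solver with absorbing threshold (Scharfetter-Gummel flux, Rannacher-
// started Crank-Nicolson), and the pair-likelihood backends built on them.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <map>
#include <functional>

using namespace Rcpp;

// ----------------------------------------------------------------------
// RNG: counter-based SplitMix64, one independent stream per trial so
// results do not depend on trial execution order.
// ----------------------------------------------------------------------

static inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Rng {
  std::uint64_t state;
  bool have;
  double cache;
  Rng(double root_seed, std::uint64_t stream) : have(false), cache(0.0) {
    std::uint64_t root = (std::uint64_t)(root_seed < 0 ? -root_seed : root_seed);
    state = splitmix64(splitmix64(root) ^ (0xA24BAED4963EE407ULL * (stream + 1ULL)));
  }
  double unif() { // open interval (0,1)
    std::uint64_t z = splitmix64(state++);
    return ((double)(z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    if (have) { have = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925287 * u2;
    cache = r * std::sin(a);
    have = true;
    return r * std::cos(a);
  }
};

// ----------------------------------------------------------------------
// Bout simulator.
// mode: 0 = none, 1 = diffusive, 2 = pulsatile.
// Beliefs start at 0; drift rho*exp(-Lambda(t)) - alpha with Lambda the
// integrated depletion exponent (slope n_active/tau); crossing detected at
// step resolution; decided agents clamp at their threshold; in pulsatile
// mode a crossing delivers an instantaneous decrement kappa_j to every
// undecided agent, recursively (cascade), all sharing the decision time.
// One normal draw per agent per step regardless of activity, so kappa = 0
// reproduces mode = none exactly at a matched seed.
// ----------------------------------------------------------------------

struct Bout {
  std::vector<double> T;      // per-agent decision time (NA -> truncated)
  std::vector<int> order;     // agent indices (0-based) in decision order
  std::vector<int> simflag;   // 1 if decision was triggered by a pulse
  bool truncated;
};

static void decide_agent(int i, double t, bool by_pulse,
                         std::vector<double>& x, const std::vector<double>& theta,
                         std::vector<char>& decided, int& n_active, Bout& out) {
  decided[i] = 1;
  x[i] = theta[i];
  out.T[i] = t;
  out.simflag[i] = by_pulse ? 1 : 0;
  out.order.push_back(i);
  --n_active;
}

static void pulse_cascade(int decider, double t,
                          std::vector<double>& x,
                          const std::vector<double>& theta,
                          const std::vector<double>& kappa,
                          std::vector<char>& decided, int& n_active, Bout& out) {
  std::vector<int> queue;
  queue.push_back(decider);
  size_t qi = 0;
  while (qi < queue.size()) {
    ++qi; // each queued decider emits one pulse of size kappa_j to every undecided j
    int n = (int)x.size();
    for (int j = 0; j < n; ++j) {
      if (!decided[j]) {
        x[j] -= kappa[j];
        if (x[j] <= theta[j]) {
          decide_agent(j, t, true, x, theta, decided, n_active, out);
          queue.push_back(j);
        }
      }
    }
  }
}

static void simulate_bout_core(int mode,
                               const std::vector<double>& theta,
                               const std::vector<double>& kappa,
                               double B, double rho, double tau, double alpha,
                               double dt, double t_max, Rng& rng, Bout& out,
                               std::vector<double>* traj_t = nullptr,
                               std::vector<double>* traj_x = nullptr,
                               std::vector<int>* traj_n = nullptr,
                               int traj_stride = 1) {
  int n = (int)theta.size();
  out.T.assign(n, NA_REAL);
  out.order.clear();
  out.simflag.assign(n, 0);
  std::vector<double> x(n, 0.0);
  std::vector<char> decided(n, 0);
  int n_active = n;
  double lambda = 0.0, t = 0.0;
  double sq = std::sqrt(2.0 * B * dt);
  long step = 0;
  bool record = (traj_t != nullptr);
  if (record) {
    traj_t->push_back(0.0);
    for (int i = 0; i < n; ++i) traj_x->push_back(0.0);
    traj_n->push_back(n_active);
  }
  while (n_active > 0 && t < t_max - 1e-12) {
    double mu = rho * std::exp(-lambda) - alpha;
    // coupling increments (diffusive only; pulses handled at crossings)
    std::vector<double> coup(n, 0.0);
    if (mode == 1) {
      double G = 0.0;
      for (int j = 0; j < n; ++j) G += decided[j] ? 0.0 : (x[j] - theta[j]);
      for (int i = 0; i < n; ++i) {
        if (!decided[i]) {
          double gi = x[i] - theta[i];
          coup[i] = kappa[i] * (G - n * gi); // = kappa_i * sum_{j!=i}(g_j - g_i)
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      double z = rng.normal(); // always drawn, even for decided agents
      if (!decided[i]) x[i] += (mu + coup[i]) * dt + sq * z;
    }
    lambda += n_active * dt / tau; // uses activity at step start
    ++step;
    t = step * dt;
    for (int i = 0; i < n; ++i) {
      if (!decided[i] && x[i] <= theta[i]) {
        decide_agent(i, t, false, x, theta, decided, n_active, out);
        if (mode == 2) pulse_cascade(i, t, x, theta, kappa, decided, n_active, out);
      }
    }
    if (record && (step % traj_stride == 0)) {
      traj_t->push_back(t);
      for (int i = 0; i < n; ++i) traj_x->push_back(x[i]);
      traj_n->push_back(n_active);
    }
  }
  out.truncated = (n_active > 0);
}

// [[Rcpp::export]]
List cpp_simulate_bouts(int mode, NumericVector theta, NumericVector kappa,
                        double B, double rho, double tau, double alpha,
                        double dt, double t_max, int n_trials, double seed) {
  int n = theta.size();
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> ka(kappa.begin(), kappa.end());
  NumericMatrix times(n_trials, n);
  IntegerMatrix flags(n_trials, n);
  IntegerMatrix order(n_trials, n);
  int truncated = 0;
  Bout b;
  for (int k = 0; k < n_trials; ++k) {
    Rng rng(seed, (std::uint64_t)k);
    simulate_bout_core(mode, th, ka, B, rho, tau, alpha, dt, t_max, rng, b);
    for (int i = 0; i < n; ++i) {
      times(k, i) = b.T[i];
      flags(k, i) = b.simflag[i];
      order(k, i) = (i < (int)b.order.size()) ? b.order[i] + 1 : NA_INTEGER;
    }
    if (b.truncated) ++truncated;
  }
  return List::create(_["times"] = times, _["simultaneous"] = flags,
                      _["order"] = order, _["n_truncated"] = truncated);
}

// [[Rcpp::export]]
List cpp_simulate_trajectory(int mode, NumericVector theta, NumericVector kappa,
                             double B, double rho, double tau, double alpha,
                             double dt, double t_max, double seed, int stride) {
  int n = theta.size();
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> ka(kappa.begin(), kappa.end());
  std::vector<double> tt, xx;
  std::vector<int> nn;
  Bout b;
  Rng rng(seed, 0ULL);
  simulate_bout_core(mode, th, ka, B, rho, tau, alpha, dt, t_max, rng, b,
                     &tt, &xx, &nn, stride);
  int nt = (int)tt.size();
  NumericMatrix states(nt, n);
  for (int r = 0; r < nt; ++r)
    for (int i = 0; i < n; ++i) states(r, i) = xx[(size_t)r * n + i];
  NumericVector T(n), tvec(tt.begin(), tt.end());
  IntegerVector nact(nn.begin(), nn.end()), ordv(n), sim(n);
  for (int i = 0; i < n; ++i) {
    T[i] = b.T[i];
    sim[i] = b.simflag[i];
    ordv[i] = (i < (int)b.order.size()) ? b.order[i] + 1 : NA_INTEGER;
  }
  return List::create(_["times"] = tvec, _["states"] = states, _["n_active"] = nact,
                      _["T"] = T, _["order"] = ordv, _["simultaneous"] = sim,
                      _["truncated"] = b.truncated);
}

// Two diffusively coupled agents, no drift (rho = alpha = 0), no absorbing
// boundary; returns samples of the half-difference (x1 - x2)/2 at the
// requested times (used to test Ornstein-Uhlenbeck noise cancellation).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_half_difference(double kappa, double B, double dt,
                                           NumericVector record_times,
                                           int n_trials, double seed) {
  int nt = record_times.size();
  NumericMatrix out(n_trials, nt);
  double t_end = record_times[nt - 1];
  long n_steps = (long)std::ceil(t_end / dt - 1e-9);
  double sq = std::sqrt(2.0 * B * dt);
  for (int k = 0; k < n_trials; ++k) {
    Rng rng(seed, (std::uint64_t)k);
    double x1 = 0.0, x2 = 0.0;
    int next_rec = 0;
    for (long s = 0; s < n_steps && next_rec < nt; ++s) {
      double c1 = kappa * (x2 - x1), c2 = kappa * (x1 - x2);
      double z1 = rng.normal(), z2 = rng.normal();
      x1 += c1 * dt + sq * z1;
      x2 += c2 * dt + sq * z2;
      double t = (s + 1) * dt;
      while (next_rec < nt && record_times[next_rec] <= t + 1e-12) {
        out(k, next_rec) = 0.5 * (x1 - x2);
        ++next_rec;
      }
    }
  }
  return out;
}

// ----------------------------------------------------------------------
// Fokker-Planck solver.
// dp/dt = -mu(t) dp/dx + D d2p/dx2 on (theta, x_max), absorbing at theta,
// reflecting at x_max. Nodes x_j = theta + j*dx, j = 1..nx (p[0] is node 1).
// Scharfetter-Gummel face flux F = (D/dx) * (B(-w) p_left - B(w) p_right),
// w = mu*dx/D, B(w) = w/(e^w - 1). Theta-scheme in time (theta_s = 1 for
// the Rannacher start-up steps, then 0.5). First-passage density read off
// the per-step absorbed mass, which the scheme conserves exactly.
// ----------------------------------------------------------------------

static inline double bern(double w) {
  double aw = std::fabs(w);
  if (aw < 1e-8) return 1.0 - 0.5 * w + w * w / 12.0;
  if (w > 500.0) return 0.0;
  if (w < -500.0) return -w;
  return w / std::expm1(w);
}

struct FpWork {
  std::vector<double> lo, di, up, rhs;
  void resize(int nx) { lo.assign(nx, 0); di.assign(nx, 0); up.assign(nx, 0); rhs.assign(nx, 0); }
};

// One theta-scheme step with drift mu (evaluated at mid-step). p updated
// in place. Returns nothing; caller tracks mass.
static void fp_step(std::vector<double>& p, double mu, double D, double dx,
                    double dt, double th, FpWork& w) {
  int nx = (int)p.size();
  double pe = mu * dx / D;
  double Bp = bern(pe), Bm = bern(-pe);
  double a = D / (dx * dx);
  // M p = (F_j - F_{j-1})/dx;  dp/dt = -(M p)
  // interior diag a*(Bm+Bp), top node diag a*Bp; sub -a*Bm; super -a*Bp.
  w.resize(nx);
  double sub = -a * Bm, sup = -a * Bp;
  for (int j = 0; j < nx; ++j) {
    double dj = (j == nx - 1) ? a * Bp : a * (Bm + Bp);
    double mp; // (M p_old)_j
    double pl = (j > 0) ? p[j - 1] : 0.0;
    double pr = (j < nx - 1) ? p[j + 1] : 0.0;
    mp = dj * p[j] + ((j > 0) ? sub * pl : 0.0) + ((j < nx - 1) ? sup * pr : 0.0);
    w.di[j] = 1.0 / dt + th * dj;
    w.lo[j] = th * sub;
    w.up[j] = th * sup;
    w.rhs[j] = p[j] / dt - (1.0 - th) * mp;
  }
  // Thomas algorithm
  for (int j = 1; j < nx; ++j) {
    double m = w.lo[j] / w.di[j - 1];
    w.di[j] -= m * w.up[j - 1];
    w.rhs[j] -= m * w.rhs[j - 1];
  }
  p[nx - 1] = w.rhs[nx - 1] / w.di[nx - 1];
  for (int j = nx - 2; j >= 0; --j)
    p[j] = (w.rhs[j] - w.up[j] * p[j + 1]) / w.di[j];
  for (int j = 0; j < nx; ++j) if (p[j] < 0) p[j] = 0.0; // SG keeps these tiny
}

static inline double mass_of(const std::vector<double>& p, double dx) {
  double s = 0.0;
  for (double v : p) s += v;
  return s * dx;
}

// Exponential-family drift mu(t) = rho * exp(-(lambda0 + m*(t-t0)/tau)) - alpha
struct DriftExp {
  double rho, tau, alpha, lambda0, m, t0;
  double operator()(double t) const {
    return rho * std::exp(-(lambda0 + m * (t - t0) / tau)) - alpha;
  }
};

// Run nsteps from t0; appends per-step FPT density (absorbed mass / dt,
// associated with step midpoints) to fout if non-null; appends survival at
// step ends to Sout if non-null.
static void fp_run(std::vector<double>& p, double t0, int nsteps, double dt,
                   double D, double dx, const std::function<double(double)>& mu,
                   int rannacher, FpWork& w,
                   std::vector<double>* fout, std::vector<double>* Sout) {
  double S_old = mass_of(p, dx);
  for (int k = 0; k < nsteps; ++k) {
    double tm = t0 + (k + 0.5) * dt;
    double th = (k < rannacher) ? 1.0 : 0.5;
    fp_step(p, mu(tm), D, dx, dt, th, w);
    double S_new = mass_of(p, dx);
    if (fout) fout->push_back((S_old - S_new) / dt);
    if (Sout) Sout->push_back(S_new);
    S_old = S_new;
  }
}

static void delta_init(std::vector<double>& p, double theta, double dx, double x0) {
  int nx = (int)p.size();
  std::fill(p.begin(), p.end(), 0.0);
  double pos = (x0 - theta) / dx; // node index (1-based grid)
  int jlo = (int)std::floor(pos);
  double frac = pos - jlo;
  // nodes are 1..nx at p[0..nx-1]
  if (jlo >= 1 && jlo <= nx) p[jlo - 1] += (1.0 - frac) / dx;
  if (jlo + 1 >= 1 && jlo + 1 <= nx) p[jlo] += frac / dx;
}

// Generic solver driven by a per-step drift vector (midpoint values).
// [[Rcpp::export]]
List cpp_fp_solve_mu(NumericVector mu_mid, double D, double theta, double x_max,
                     int nx, double dt, NumericVector p0, double x0) {
  int nt = mu_mid.size();
  double dx = (x_max - theta) / (nx + 0.0); // node nx sits at x_max
  std::vector<double> p(nx, 0.0);
  if (p0.size() == nx) {
    for (int j = 0; j < nx; ++j) p[j] = p0[j];
  } else {
    delta_init(p, theta, dx, x0);
  }
  FpWork w;
  std::vector<double> f, S;
  f.reserve(nt); S.reserve(nt);
  double S_old = mass_of(p, dx);
  for (int k = 0; k < nt; ++k) {
    double th = (k < 2) ? 1.0 : 0.5;
    fp_step(p, mu_mid[k], D, dx, dt, th, w);
    double S_new = mass_of(p, dx);
    f.push_back((S_old - S_new) / dt);
    S.push_back(S_new);
    S_old = S_new;
  }
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["S"] = NumericVector(S.begin(), S.end()),
                      _["p_final"] = NumericVector(p.begin(), p.end()),
                      _["dx"] = dx);
}

// First-passage density for the exponential-family drift (used by the
// limiting models). m is the depletion exponent multiplier (number of
// active foragers), D the diffusion coefficient (dx = mu dt + sqrt(2D) dW).
// [[Rcpp::export]]
List cpp_fpt_exp_drift(double rho, double tau, double alpha, double m,
                       double lambda0, double D, double theta, double x_max,
                       int nx, double dt, double t_max, double x0) {
  int nt = (int)std::ceil(t_max / dt - 1e-9);
  double dx = (x_max - theta) / (nx + 0.0);
  std::vector<double> p(nx, 0.0);
  delta_init(p, theta, dx, x0);
  DriftExp mu{rho, tau, alpha, lambda0, m, 0.0};
  FpWork w;
  std::vector<double> f, S;
  f.reserve(nt); S.reserve(nt);
  fp_run(p, 0.0, nt, dt, D, dx, mu, 2, w, &f, &S);
  NumericVector tm(nt);
  for (int k = 0; k < nt; ++k) tm[k] = (k + 0.5) * dt;
  return List::create(_["t"] = tm,
                      _["f"] = NumericVector(f.begin(), f.end()),
                      _["S"] = NumericVector(S.begin(), S.end()),
                      _["p_final"] = NumericVector(p.begin(), p.end()),
                      _["dx"] = dx);
}

// linear interpolation of per-step midpoint values
static double interp_mid(const std::vector<double>& f, double dt, double t) {
  int n = (int)f.size();
  if (n == 0) return 0.0;
  double pos = t / dt - 0.5;
  if (pos <= 0.0) return f[0];
  if (pos >= n - 1) return f[n - 1];
  int j = (int)std::floor(pos);
  double fr = pos - j;
  return f[j] * (1.0 - fr) + f[j + 1] * fr;
}

// Shift a density down by kappa (toward the absorbing boundary at theta):
// q_new(x) = q_old(x + kappa), mass pushed below theta is returned (atom).
static double shift_density(std::vector<double>& p, double dx, double kappa) {
  if (kappa <= 0.0) return 0.0;
  int nx = (int)p.size();
  double S_before = mass_of(p, dx);
  std::vector<double> q(nx, 0.0);
  double off = kappa / dx;
  for (int j = 0; j < nx; ++j) {
    double pos = j + off; // source index on p
    int jl = (int)std::floor(pos);
    double fr = pos - jl;
    double v = 0.0;
    if (jl >= 0 && jl < nx) v += p[jl] * (1.0 - fr);
    if (jl + 1 >= 0 && jl + 1 < nx) v += p[jl + 1] * fr;
    q[j] = v;
  }
  p.swap(q);
  return S_before - mass_of(p, dx);
}

// Joint log-likelihood of ordered departure-time pairs under the
// no-coupling (model = 0) or pulsatile (model = 1) class.
// Both agents evolve i.i.d. under the two-forager drift until the first
// decision; the survivor's (unnormalised) interior density is then
// propagated under the one-forager drift -- shifted down by kappa first in
// the pulsatile case, where the shifted-out mass is the probability atom
// of a simultaneous departure.
// Pairs are grouped on snapshots taken every `snap_stride` PDE steps at or
// before t1 (a path absorbed between the snapshot and t1 contributes
// nothing to the later flux, so an earlier snapshot is exact up to the
// O(stride*dt) sliver of drift mismatch); each group is propagated once.
// [[Rcpp::export]]
NumericVector cpp_pair_loglik_fp(int model, NumericVector t1, NumericVector t2,
                                 LogicalVector simflag, double theta,
                                 double kappa, double B, double rho, double tau,
                                 double alpha, double dt, int nx, double x_max,
                                 double sim_tol, double dens_floor,
                                 int snap_stride) {
  int K = t1.size();
  NumericVector out(K);
  double D = B; // each agent carries noise sqrt(2B) dW
  double dx = (x_max - theta) / (nx + 0.0);
  double t1max = 0.0;
  for (int k = 0; k < K; ++k) if (t1[k] > t1max) t1max = t1[k];
  int nt1 = (int)std::ceil(t1max / dt - 1e-9) + 1;
  if (snap_stride < 1) snap_stride = 1;
  // snapshot index per pair: largest stride multiple <= t1/dt (>= 1)
  std::vector<int> snap_idx(K);
  std::map<int, std::vector<int> > groups; // snapshot step -> pair ids
  for (int k = 0; k < K; ++k) {
    int idx = (int)std::floor(t1[k] / dt + 1e-9);
    idx = (idx / snap_stride) * snap_stride;
    if (idx < 1) idx = 1;
    snap_idx[k] = idx;
    groups[idx].push_back(k);
  }
  // phase 1: both foragers active (depletion exponent 2)
  std::vector<double> p(nx, 0.0);
  delta_init(p, theta, dx, 0.0);
  DriftExp mu2{rho, tau, alpha, 0.0, 2.0, 0.0};
  FpWork w;
  std::vector<double> f1;
  f1.reserve(nt1);
  std::map<int, std::vector<double> > snaps;
  double S_old = mass_of(p, dx);
  for (int s = 1; s <= nt1; ++s) {
    double tm = (s - 0.5) * dt;
    double th = (s <= 2) ? 1.0 : 0.5;
    fp_step(p, mu2(tm), D, dx, dt, th, w);
    double S_new = mass_of(p, dx);
    f1.push_back((S_old - S_new) / dt);
    S_old = S_new;
    if (groups.count(s)) snaps[s] = p;
  }
  for (std::map<int, std::vector<int> >::iterator it = groups.begin();
       it != groups.end(); ++it) {
    int s0 = it->first;
    std::vector<int>& ids = it->second;
    double ts = s0 * dt;
    std::vector<double> q = snaps[s0];
    double atom = 0.0;
    if (model == 1 && kappa > 0.0) atom = shift_density(q, dx, kappa);
    // longest propagation needed in this group. An observation within the
    // simultaneity tolerance scores a *probability* under every class
    // (atom + local continuous mass), keeping atom-carrying and purely
    // continuous classes dimensionally comparable; its continuous part is
    // evaluated at offset max(sim_tol, dt) past t1.
    double target_max = 0.0;
    for (size_t i = 0; i < ids.size(); ++i) {
      int k = ids[i];
      bool simult = (simflag[k] == TRUE) || (t2[k] - t1[k] <= sim_tol);
      double target = simult ? (t1[k] - ts) + std::max(sim_tol, dt)
                             : (t2[k] - ts);
      if (target > target_max) target_max = target;
    }
    std::vector<double> g;
    DriftExp mu1{rho, tau, alpha, 2.0 * ts / tau, 1.0, ts};
    int nst = (int)std::ceil(target_max / dt - 1e-9);
    if (nst < 1) nst = 1;
    g.reserve(nst);
    fp_run(q, ts, nst, dt, D, dx, mu1, 2, w, &g, nullptr);
    for (size_t i = 0; i < ids.size(); ++i) {
      int k = ids[i];
      double fa = interp_mid(f1, dt, t1[k]);
      if (fa < dens_floor) fa = dens_floor;
      bool simult = (simflag[k] == TRUE) || (t2[k] - t1[k] <= sim_tol);
      if (simult) {
        double gv = interp_mid(g, dt, (t1[k] - ts) + std::max(sim_tol, dt));
        double prob = atom + gv * std::max(sim_tol, 0.0);
        if (prob < dens_floor) prob = dens_floor;
        out[k] = std::log(2.0) + std::log(fa) + std::log(prob);
      } else {
        double gv = interp_mid(g, dt, t2[k] - ts);
        if (gv < dens_floor) gv = dens_floor;
        out[k] = std::log(2.0) + std::log(fa) + std::log(gv);
      }
    }
  }
  return out;
}

// Group (last-forager) departure-time density for two uncoupled foragers:
// first-decider flux from the two-forager solve, survivor propagated under
// the one-forager drift from snapshots taken every `stride` steps.
// [[Rcpp::export]]
List cpp_nc_group_fpt(double rho, double tau, double alpha, double theta,
                      double B, double dt, int nx, double x_max, double t_max,
                      int stride) {
  double D = B;
  double dx = (x_max - theta) / (nx + 0.0);
  int nt = (int)std::ceil(t_max / dt - 1e-9);
  std::vector<double> p(nx, 0.0);
  delta_init(p, theta, dx, 0.0);
  DriftExp mu2{rho, tau, alpha, 0.0, 2.0, 0.0};
  FpWork w;
  std::vector<double> f1, S1, g(nt, 0.0);
  f1.reserve(nt); S1.reserve(nt);
  std::vector<std::pair<int, std::vector<double> > > snaps;
  double S_old = mass_of(p, dx);
  for (int s = 1; s <= nt; ++s) {
    double tm = (s - 0.5) * dt;
    double th = (s <= 2) ? 1.0 : 0.5;
    fp_step(p, mu2(tm), D, dx, dt, th, w);
    double S_new = mass_of(p, dx);
    f1.push_back((S_old - S_new) / dt);
    S1.push_back(S_new);
    S_old = S_new;
    if (s % stride == 0 && S_new > 1e-12)
      snaps.push_back(std::make_pair(s, p));
  }
  double wgt = stride * dt;
  for (size_t si = 0; si < snaps.size(); ++si) {
    int s0 = snaps[si].first;
    double ts = s0 * dt;
    // first-decider density on the snapshot window: 2 * f(t) (unnormalised
    // survivor carries the S factor)
    double fd = 2.0 * interp_mid(f1, dt, ts - 0.5 * wgt);
    if (fd <= 0) continue;
    std::vector<double> q = snaps[si].second;
    DriftExp mu1{rho, tau, alpha, 2.0 * ts / tau, 1.0, ts};
    int nst = nt - s0;
    if (nst < 1) continue;
    std::vector<double> flux;
    flux.reserve(nst);
    fp_run(q, ts, nst, dt, D, dx, mu1, 2, w, &flux, nullptr);
    for (int j = 0; j < nst; ++j) g[s0 + j] += fd * flux[j] * wgt;
  }
  NumericVector tm(nt);
  for (int k = 0; k < nt; ++k) tm[k] = (k + 0.5) * dt;
  return List::create(_["t"] = tm,
                      _["g"] = NumericVector(g.begin(), g.end()),
                      _["f_single"] = NumericVector(f1.begin(), f1.end()),
                      _["S_single"] = NumericVector(S1.begin(), S1.end()));
}

// Simulation + 2D kernel density estimate of the ordered-pair density for
// the diffusively coupled class, in coordinates (u, v) = (T1, T2 - T1)
// with kernel reflection across v = 0. Deterministic given `seed`.
// [[Rcpp::export]]
NumericVector cpp_pair_loglik_diffusive(NumericVector t1, NumericVector t2,
                                        double theta, double kappa, double B,
                                        double rho, double tau, double alpha,
                                        double dt, double t_max, int n_sims,
                                        double seed, double dens_floor,
                                        double sim_tol) {
  std::vector<double> th(2, theta), ka(2, kappa);
  std::vector<double> u, v;
  u.reserve(n_sims); v.reserve(n_sims);
  Bout b;
  for (int k = 0; k < n_sims; ++k) {
    Rng rng(seed, (std::uint64_t)k);
    simulate_bout_core(1, th, ka, B, rho, tau, alpha, dt, t_max, rng, b);
    if (b.truncated) continue;
    double a = std::min(b.T[0], b.T[1]);
    double c = std::max(b.T[0], b.T[1]);
    u.push_back(a);
    v.push_back(c - a);
  }
  int M = (int)u.size();
  int K = t1.size();
  NumericVector out(K);
  if (M < 10) {
    for (int k = 0; k < K; ++k) out[k] = std::log(dens_floor);
    return out;
  }
  double mu_u = 0, mu_v = 0;
  for (int i = 0; i < M; ++i) { mu_u += u[i]; mu_v += v[i]; }
  mu_u /= M; mu_v /= M;
  double s_u = 0, s_v = 0;
  for (int i = 0; i < M; ++i) {
    s_u += (u[i] - mu_u) * (u[i] - mu_u);
    s_v += (v[i] - mu_v) * (v[i] - mu_v);
  }
  s_u = std::sqrt(s_u / (M - 1));
  s_v = std::sqrt(s_v / (M - 1));
  double fac = std::pow((double)M, -1.0 / 6.0); // Silverman-type 2D rule
  double hu = std::max(s_u * fac, dt);
  double hv = std::max(s_v * fac, dt);
  double norm = 1.0 / (2.0 * M_PI * hu * hv * M);
  for (int k = 0; k < K; ++k) {
    double a = t1[k], c = t2[k] - t1[k];
    double dens = 0.0;
    for (int i = 0; i < M; ++i) {
      double zu = (a - u[i]) / hu;
      if (std::fabs(zu) > 8.0) continue;
      double ku = std::exp(-0.5 * zu * zu);
      double z1 = (c - v[i]) / hv, z2 = (c + v[i]) / hv;
      double kv = std::exp(-0.5 * z1 * z1);
      if (std::fabs(z2) < 8.0) kv += std::exp(-0.5 * z2 * z2);
      dens += ku * kv;
    }
    dens *= norm;
    // observations within the simultaneity tolerance score the local
    // probability mass (density x tolerance), matching the atom-carrying
    // pulsatile class dimensionally
    if (t2[k] - t1[k] <= sim_tol) dens *= std::max(sim_tol, 0.0);
    if (dens < dens_floor) dens = dens_floor;
    out[k] = std::log(dens);
  }
  return out;
}
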