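// Fused neighbor-list / alchemy / toy-potential / Langevin engine.
//
// Everything user-facing lives in R; these kernels exist because the MD
// inner loop (rebuild pair list -> shift distances -> energy/forces ->
// BAOAB update, every step) is the hot path. The R-level neighbor-list +
// energy route is kept as an independent implementation and the test suite
// checks the two agree.
//
// Internal units: A, kcal/mol, amu, ps, K.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// acceleration (A/ps^2) per (kcal/mol/A / amu); 1 cal = 4.184 J exactly
static const double FCONV = 418.4;

// ---- minimum image -------------------------------------------------------

static inline void min_image(double dx[3], const double box[3]) {
  for (int k = 0; k < 3; ++k) dx[k] -= box[k] * std::round(dx[k] / box[k]);
}

// ---- lambda-dependent distance shifting ----------------------------------
// scheme 1: d + lam*rcut                       (linear, beyond cutoff)
// scheme 2: d + lam*max(0, rcut-d) + lam*eps   (linear, to cutoff)
// scheme 3: sqrt(d^2 + (lam*rcut)^2)           (4D, beyond cutoff)
// scheme 4: sqrt(d^2 + lam*max(rcut^2-d^2,0)) + lam*eps  (4D, to cutoff)
// The guard eps is scaled by lam so lam=0 is an exact identity while lam=1
// still clears the cutoff by an eps-order excess.

static inline double shift_d(double d, double rcut, int scheme, double lam,
                             double eps) {
  switch (scheme) {
  case 1: return d + lam * rcut;
  case 2: return d + lam * std::max(0.0, rcut - d) + lam * eps;
  case 3: return std::sqrt(d * d + lam * lam * rcut * rcut);
  case 4: return std::sqrt(d * d + lam * std::max(rcut * rcut - d * d, 0.0)) +
                 lam * eps;
  }
  return d;
}

// d(shifted)/d(true distance): the chain factor carrying forces back onto
// the real coordinates (the fictitious 4th component exerts no force).
static inline double chain_f(double d, double rcut, int scheme, double lam) {
  switch (scheme) {
  case 1: return 1.0;
  case 2: return d < rcut ? 1.0 - lam : 1.0;
  case 3: {
    double g = std::sqrt(d * d + lam * lam * rcut * rcut);
    return g > 0 ? d / g : (lam > 0 ? 0.0 : 1.0);
  }
  case 4: {
    if (d >= rcut) return 1.0;
    double g2 = d * d + lam * (rcut * rcut - d * d);
    double g = std::sqrt(g2);
    return g > 0 ? d * (1.0 - lam) / g : (lam > 0 ? 0.0 : 1.0);
  }
  }
  return 1.0;
}

// [[Rcpp::export]]
NumericVector cpp_shift_distance(NumericVector d, double rcut, int scheme,
                                 double lam, double eps) {
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = shift_d(d[i], rcut, scheme, lam, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_chain_factor(NumericVector d, double rcut, int scheme,
                               double lam) {
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = chain_f(d[i], rcut, scheme, lam);
  return out;
}

// ---- toy pair potential: LJ x cubic switch, zero at and beyond rcut ------

static inline double pair_u(double d, double eps, double sig, double rcut,
                            double ron, double *du) {
  *du = 0.0;
  if (eps <= 0.0 || d >= rcut) return 0.0;
  double sr2 = sig * sig / (d * d);
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double lj = 4.0 * eps * (sr12 - sr6);
  double ljd = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / d;
  if (d <= ron) {
    *du = ljd;
    return lj;
  }
  double w = rcut - ron;
  double t = (d - ron) / w;
  double s = 1.0 - t * t * (3.0 - 2.0 * t);
  double sd = -6.0 * t * (1.0 - t) / w;
  *du = ljd * s + lj * sd;
  return lj * s;
}

// ---- pair classification --------------------------------------------------
// selector 0: no pair modified
// selector 1: modified iff exactly one endpoint is a solute atom
// selector 2: per-atom decoupling; mode 0 = ordinary, 1 = effective lambda
//             = lam (vanishing), 2 = effective lambda = 1-lam (appearing);
//             pairs between two mode>0 atoms are excluded outright
// return: -1 exclude pair, 0 unmodified, 1 modified (lam_eff set)

static inline int classify(int i, int j, int selector, const int *sol,
                           const int *mode, double lam, double *lam_eff) {
  *lam_eff = lam;
  if (selector == 1) return (sol[i] + sol[j] == 1) ? 1 : 0;
  if (selector == 2) {
    bool ai = mode[i] > 0, aj = mode[j] > 0;
    if (ai && aj) return -1;
    if (!ai && !aj) return 0;
    int m = ai ? mode[i] : mode[j];
    *lam_eff = (m == 1) ? lam : 1.0 - lam;
    return 1;
  }
  return 0;
}

// ---- full energy / force evaluation --------------------------------------

struct EvalCtx {
  const double *pos; int n;
  double box[3];
  const double *epsa, *siga;     // per-atom LJ parameters (pre-combined later)
  double rcut, ron, eps_guard;
  int scheme; double lam;
  int selector;
  const int *sol, *mode, *masked;
  bool float32;
  // restraints (anchor point, or anchor atom when ratom2 >= 0)
  int nres;
  const int *ratom; const int *ratom2;
  const double *ranch; const double *rr0; const double *rkf;
};

// returns false on overlap of an unmodified pair (d < 1e-6 A)
static bool energy_forces(const EvalCtx &c, double *E, double *F, int *bad) {
  *E = 0.0;
  *bad = -1;
  if (F) for (int k = 0; k < 3 * c.n; ++k) F[k] = 0.0;
  for (int i = 0; i < c.n - 1; ++i) {
    if (c.masked[i]) continue;
    for (int j = i + 1; j < c.n; ++j) {
      if (c.masked[j]) continue;
      double dx[3];
      for (int k = 0; k < 3; ++k) dx[k] = c.pos[3 * j + k] - c.pos[3 * i + k];
      min_image(dx, c.box);
      double d2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
      if (d2 >= c.rcut * c.rcut) continue;   // not a neighbor-list entry
      double d = std::sqrt(d2);
      double lam_eff;
      int cls = classify(i, j, c.selector, c.sol, c.mode, c.lam, &lam_eff);
      if (cls < 0) continue;
      double dp = d, cf = 1.0;
      if (cls == 1) {
        dp = shift_d(d, c.rcut, c.scheme, lam_eff, c.eps_guard);
        cf = chain_f(d, c.rcut, c.scheme, lam_eff);
      }
      double eps = std::sqrt(c.epsa[i] * c.epsa[j]);
      double sig = 0.5 * (c.siga[i] + c.siga[j]);
      if (c.float32) dp = (double)(float)dp;
      double du;
      double u = pair_u(dp, eps, sig, c.rcut, c.ron, &du);
      if (c.float32) { u = (double)(float)u; du = (double)(float)du; }
      *E += u;
      if (F) {
        if (d < 1e-6) {
          if (cls == 0 && eps > 0.0) { *bad = i; return false; } // hard overlap
          continue;  // modified pair at d~0: direction undefined, |f| ~ cf ~ 0
        }
        double fac = du * cf / d;   // dU/dd' * dd'/dd * (1/d) on displacement
        for (int k = 0; k < 3; ++k) {
          double fk = fac * dx[k];
          F[3 * i + k] += fk;       // force on i is -dU/dx_i = +fac*dx
          F[3 * j + k] -= fk;
        }
      }
    }
  }
  // flat-bottom restraints: 0 inside r0, harmonic outside
  for (int r = 0; r < c.nres; ++r) {
    int a = c.ratom[r];
    int b = c.ratom2[r];
    double dx[3];
    for (int k = 0; k < 3; ++k) {
      double ref = b >= 0 ? c.pos[3 * b + k] : c.ranch[3 * r + k];
      dx[k] = c.pos[3 * a + k] - ref;
    }
    min_image(dx, c.box);
    double d = std::sqrt(dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
    if (d > c.rr0[r]) {
      double ex = d - c.rr0[r];
      *E += 0.5 * c.rkf[r] * ex * ex;
      if (F && d > 1e-12) {
        double fac = -c.rkf[r] * ex / d;
        for (int k = 0; k < 3; ++k) {
          F[3 * a + k] += fac * dx[k];
          if (b >= 0) F[3 * b + k] -= fac * dx[k];
        }
      }
    }
  }
  return true;
}

static EvalCtx make_ctx(const NumericMatrix &pos, const NumericVector &box,
                        const NumericVector &epsa, const NumericVector &siga,
                        double rcut, double switch_start, double eps_guard,
                        int scheme, double lam, int selector,
                        const IntegerVector &sol, const IntegerVector &mode,
                        const IntegerVector &masked, bool float32,
                        const IntegerVector &ratom, const IntegerVector &ratom2,
                        const NumericMatrix &ranch,
                        const NumericVector &rr0, const NumericVector &rkf,
                        std::vector<double> &posbuf,
                        std::vector<double> &anchbuf) {
  EvalCtx c;
  c.n = pos.nrow();
  posbuf.resize(3 * c.n);
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k) posbuf[3 * i + k] = pos(i, k);
  c.pos = posbuf.data();
  for (int k = 0; k < 3; ++k) c.box[k] = box[k];
  c.epsa = epsa.begin(); c.siga = siga.begin();
  c.rcut = rcut; c.ron = switch_start * rcut; c.eps_guard = eps_guard;
  c.scheme = scheme; c.lam = lam; c.selector = selector;
  c.sol = sol.begin(); c.mode = mode.begin(); c.masked = masked.begin();
  c.float32 = float32;
  c.nres = ratom.size();
  anchbuf.resize(3 * std::max(1, c.nres));
  for (int r = 0; r < c.nres; ++r)
    for (int k = 0; k < 3; ++k) anchbuf[3 * r + k] = ranch(r, k);
  c.ratom = ratom.begin(); c.ratom2 = ratom2.begin(); c.ranch = anchbuf.data();
  c.rr0 = rr0.begin(); c.rkf = rkf.begin();
  return c;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector box,
                       NumericVector epsa, NumericVector siga, double rcut,
                       double switch_start, double eps_guard, int scheme,
                       double lam, int selector, IntegerVector sol,
                       IntegerVector mode, IntegerVector masked, bool float32,
                       IntegerVector ratom, IntegerVector ratom2,
                       NumericMatrix ranch,
                       NumericVector rr0, NumericVector rkf,
                       bool want_forces) {
  std::vector<double> pb, ab;
  EvalCtx c = make_ctx(pos, box, epsa, siga, rcut, switch_start, eps_guard,
                       scheme, lam, selector, sol, mode, masked, float32,
                       ratom, ratom2, ranch, rr0, rkf, pb, ab);
  double E;
  int bad;
  std::vector<double> F(want_forces ? 3 * c.n : 0);
  bool ok = energy_forces(c, &E, want_forces ? F.data() : nullptr, &bad);
  if (!ok)
    stop("overlapping unmodified atom pair (d < 1e-6 A) involving atom %d",
         bad + 1);
  List out = List::create(Named("energy") = E);
  if (want_forces) {
    NumericMatrix Fm(c.n, 3);
    for (int i = 0; i < c.n; ++i)
      for (int k = 0; k < 3; ++k) Fm(i, k) = F[3 * i + k];
    out["forces"] = Fm;
  }
  return out;
}

// ---- neighbor list --------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_build_nl(NumericMatrix pos, NumericVector box, double rcut) {
  int n = pos.nrow();
  std::vector<double> rows;
  double b[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx[3];
      for (int k = 0; k < 3; ++k) dx[k] = pos(j, k) - pos(i, k);
      min_image(dx, b);
      double d2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
      if (d2 < rcut * rcut) {
        rows.push_back(i + 1);
        rows.push_back(j + 1);
        rows.push_back(std::sqrt(d2));
        rows.push_back(dx[0]);
        rows.push_back(dx[1]);
        rows.push_back(dx[2]);
      }
    }
  }
  int m = rows.size() / 6;
  NumericMatrix out(m, 6);
  for (int r = 0; r < m; ++r)
    for (int k = 0; k < 6; ++k) out(r, k) = rows[6 * r + k];
  colnames(out) = CharacterVector::create("i", "j", "d", "dx", "dy", "dz");
  return out;
}

// ---- BAOAB Langevin window ------------------------------------------------
// dt ps, friction 1/ps, kT kcal/mol. Uses R's RNG (seed set from R).
// spike_step >= 0 injects a large random force at that step (fault-injection
// hook used to exercise the instability-retry path).

// [[Rcpp::export]]
List cpp_run_window(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                    NumericVector box, NumericVector epsa, NumericVector siga,
                    double rcut, double switch_start, double eps_guard,
                    int scheme, double lam, int selector, IntegerVector sol,
                    IntegerVector mode, IntegerVector masked, bool float32,
                    IntegerVector ratom, IntegerVector ratom2,
                    NumericMatrix ranch, NumericVector rr0,
                    NumericVector rkf, double dt, double friction, double kT,
                    int n_steps, int save_interval, int spike_step,
                    double spike_mag) {
  std::vector<double> pb, ab;
  EvalCtx c = make_ctx(pos, box, epsa, siga, rcut, switch_start, eps_guard,
                       scheme, lam, selector, sol, mode, masked, float32,
                       ratom, ratom2, ranch, rr0, rkf, pb, ab);
  int n = c.n;
  std::vector<double> x(pb), v(3 * n), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) v[3 * i + k] = vel(i, k);

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  int n_frames = n_steps / save_interval;
  NumericMatrix frames(n_frames * n, 3);
  NumericVector energies(n_frames);

  double E;
  int bad;
  c.pos = x.data();
  bool ok = energy_forces(c, &E, F.data(), &bad);
  int fail_step = -1, fail_atom = -1;
  int fi = 0;

  for (int step = 0; ok && step < n_steps; ++step) {
    if (step == spike_step) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) F[3 * i + k] += spike_mag * norm_rand();
    }
    // B
    for (int i = 0; i < n; ++i) {
      double a = FCONV / mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += 0.5 * dt * a * F[3 * i + k];
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (friction > 0.0) {
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(kT * FCONV / mass[i]);
        for (int k = 0; k < 3; ++k)
          v[3 * i + k] = c1 * v[3 * i + k] + c2 * sd * norm_rand();
      }
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // B with fresh forces
    ok = energy_forces(c, &E, F.data(), &bad);
    if (!ok || !std::isfinite(E)) {
      ok = false; fail_step = step; fail_atom = bad;
      break;
    }
    for (int i = 0; i < n; ++i) {
      double a = FCONV / mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += 0.5 * dt * a * F[3 * i + k];
    }
    // blow-up detector: non-finite state, or velocities far beyond any
    // physically attainable value (thermal speeds are a few A/ps)
    for (int i = 0; i < 3 * n && ok; ++i)
      if (!std::isfinite(x[i]) || !std::isfinite(v[i]) ||
          std::fabs(v[i]) > 1e4) {
        ok = false; fail_step = step; fail_atom = i / 3;
      }
    if (ok && (step + 1) % save_interval == 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) frames(fi * n + i, k) = x[3 * i + k];
      energies[fi] = E;
      ++fi;
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      xout(i, k) = x[3 * i + k];
      vout(i, k) = v[3 * i + k];
    }
  return List::create(Named("ok") = ok, Named("frames") = frames,
                      Named("energies") = energies, Named("n_frames") = fi,
                      Named("positions") = xout, Named("velocities") = vout,
                      Named("fail_step") = fail_step,
                      Named("fail_atom") = fail_atom + 1);
}

// ---- steepest-descent relaxation (fixture generation) ---------------------

// [[Rcpp::export]]
NumericMatrix cpp_relax(NumericMatrix pos, NumericVector box,
                        NumericVector epsa, NumericVector siga, double rcut,
                        double switch_start, int n_iter, double max_disp) {
  int n = pos.nrow();
  IntegerVector sol(n), mode(n), masked(n);
  IntegerVector ratom(0), ratom2(0);
  NumericMatrix ranch(0, 3);
  NumericVector rr0(0), rkf(0);
  std::vector<double> pb, ab;
  EvalCtx c = make_ctx(pos, box, epsa, siga, rcut, switch_start, 0.0, 1, 0.0,
                       0, sol, mode, masked, false, ratom, ratom2, ranch,
                       rr0, rkf, pb, ab);
  std::vector<double> x(pb), F(3 * n);
  c.pos = x.data();
  double E;
  int bad;
  for (int it = 0; it < n_iter; ++it) {
    energy_forces(c, &E, F.data(), &bad);
    double fmax = 0.0;
    for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::fabs(F[i]));
    if (fmax < 1e-4) break;
    double scale = max_disp / fmax;
    for (int i = 0; i < 3 * n; ++i) x[i] += scale * F[i];
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return out;
}
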