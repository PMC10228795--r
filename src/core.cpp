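// Stiff core for the 4-species wound-signalling reaction-diffusion model.
//
// State layout: interleaved by compartment, u[4*i + s] with
// s = 0 EIG, 1 JNK, 2 JAK, 3 UPD.  Only EIG and UPD diffuse, so the
// Jacobian is banded with half-bandwidth 4; linear solves use LAPACK's
// banded LU (dgbtrf/dgbtrs).

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  double gamma, kdeg_jnk, kdeg_jak, kdeg_upd;
  double kact_eig, kact_jnk, kact_jak, kact_upd;
  double km_eig, km_jnk, km_jak, km_upd;
  double kinh_jak_by_jnk, kinh_jnk_by_jak, d;
  double n1, n2, n3, n4, ni1, ni2;
};

Params unpack(const NumericVector& q) {
  if (q.size() != 21) stop("parameter vector must have 21 entries");
  Params p;
  p.gamma = q[0];  p.kdeg_jnk = q[1]; p.kdeg_jak = q[2]; p.kdeg_upd = q[3];
  p.kact_eig = q[4]; p.kact_jnk = q[5]; p.kact_jak = q[6]; p.kact_upd = q[7];
  p.km_eig = q[8]; p.km_jnk = q[9]; p.km_jak = q[10]; p.km_upd = q[11];
  p.kinh_jak_by_jnk = q[12]; p.kinh_jnk_by_jak = q[13]; p.d = q[14];
  p.n1 = q[15]; p.n2 = q[16]; p.n3 = q[17]; p.n4 = q[18];
  p.ni1 = q[19]; p.ni2 = q[20];
  for (int i = 0; i < 21; ++i)
    if (!R_finite(q[i])) stop("non-finite parameter value");
  return p;
}

inline double pos(double x) { return x > 0.0 ? x : 0.0; }

// Hill activation u^n / (Kn + u^n) and its derivative wrt u (Kn = K^n
// precomputed once per run).
inline void hill(double u, double Kn, double n, double& h, double& dh) {
  double un = std::pow(u, n);
  double den = Kn + un;
  if (den <= 0.0) { h = 0.0; dh = 0.0; return; }
  h = un / den;
  dh = n * Kn * std::pow(u, n - 1.0) / (den * den);
}

// Second-difference operator, dx = 1/N.  boundary: 0 zero-flux, 1 absorbing.
inline double lap_at(const double* u, int i, int N, int stride,
                     double idx2, int boundary) {
  double left  = (i > 0)     ? u[(i - 1) * stride] : (boundary ? 0.0 : u[i * stride]);
  double right = (i < N - 1) ? u[(i + 1) * stride] : (boundary ? 0.0 : u[i * stride]);
  return (left - 2.0 * u[i * stride] + right) * idx2;
}

struct Model {
  Params p;
  int N;
  std::vector<double> wound;  // indicator per compartment
  bool mutual;
  int boundary;               // 0 zero-flux, 1 absorbing
  double idx2;                // 1/dx^2
  double kmn1, kmn2, kmn3, kmn4, kiA, kiB;  // cached constant powers

  Model(const NumericVector& q, const NumericVector& wound_ind,
        bool mutual_, int boundary_)
      : p(unpack(q)), N(wound_ind.size()),
        wound(wound_ind.begin(), wound_ind.end()),
        mutual(mutual_), boundary(boundary_) {
    double dx = 1.0 / N;
    idx2 = 1.0 / (dx * dx);
    kmn1 = std::pow(p.km_eig, p.n1);
    kmn2 = std::pow(p.km_jnk, p.n2);
    kmn3 = std::pow(p.km_jak, p.n3);
    kmn4 = std::pow(p.km_upd, p.n4);
    kiA = std::pow(p.kinh_jnk_by_jak, p.ni1);
    kiB = std::pow(p.kinh_jak_by_jnk, p.ni2);
  }

  int n() const { return 4 * N; }

  void rhs(const double* u, double* f) const {
    for (int i = 0; i < N; ++i) {
      const double E = pos(u[4 * i]), J = pos(u[4 * i + 1]);
      const double S = pos(u[4 * i + 2]), U = pos(u[4 * i + 3]);
      double h1, dh1, g2, dg2, h3, dh3, h4, dh4;
      hill(J, kmn1, p.n1, h1, dh1);
      hill(E, kmn2, p.n2, g2, dg2);
      hill(S, kmn3, p.n3, h3, dh3);
      hill(J, kmn4, p.n4, h4, dh4);
      double A = 1.0 + kiA * std::pow(S, p.ni1);
      double B = mutual ? 1.0 + kiB * std::pow(J, p.ni2) : 1.0;
      f[4 * i]     = p.gamma * (wound[i] - E + p.kact_eig * h1)
                   + lap_at(u, i, N, 4, idx2, boundary);
      f[4 * i + 1] = p.gamma * (1.0 - p.kdeg_jnk * J + p.kact_jnk * g2 / A);
      f[4 * i + 2] = p.gamma * (1.0 - p.kdeg_jak * S + p.kact_jak * U * h3 / B);
      f[4 * i + 3] = p.gamma * (1.0 - p.kdeg_upd * U + p.kact_upd * h4)
                   + p.d * lap_at(u + 3, i, N, 4, idx2, boundary);
    }
  }

  // Banded Jacobian in LAPACK band storage for dgbtrf:
  // AB(kl+ku+i-j, j) = J(i,j), ldab = 2*kl+ku+1 = 13, kl = ku = 4.
  // scale/shift: writes  diag_shift*I + scale*J  (implicit Euler uses
  // scale = -dt, diag_shift = 1; Newton uses scale = 1, diag_shift = 0).
  void jac_banded(const double* u, double* AB, double diag_shift,
                  double scale) const {
    const int kl = 4, ku = 4, ldab = 2 * kl + ku + 1;
    const int n4 = n();
    std::fill(AB, AB + (size_t)ldab * n4, 0.0);
    auto at = [&](int i, int j) -> double& {
      return AB[(size_t)j * ldab + (kl + ku + i - j)];
    };
    for (int i = 0; i < N; ++i) {
      const double E = pos(u[4 * i]), J = pos(u[4 * i + 1]);
      const double S = pos(u[4 * i + 2]), U = pos(u[4 * i + 3]);
      double h1, dh1, g2, dg2, h3, dh3, h4, dh4;
      hill(J, kmn1, p.n1, h1, dh1);
      hill(E, kmn2, p.n2, g2, dg2);
      hill(S, kmn3, p.n3, h3, dh3);
      hill(J, kmn4, p.n4, h4, dh4);
      double A = 1.0 + kiA * std::pow(S, p.ni1);
      double dA = kiA * p.ni1 * std::pow(S, p.ni1 - 1.0);
      double B = 1.0, dB = 0.0;
      if (mutual) {
        B = 1.0 + kiB * std::pow(J, p.ni2);
        dB = kiB * p.ni2 * std::pow(J, p.ni2 - 1.0);
      }
      const int iE = 4 * i, iJ = 4 * i + 1, iS = 4 * i + 2, iU = 4 * i + 3;
      // reaction block
      double diff_diag = -2.0 * idx2;
      if (boundary == 0 && (i == 0 || i == N - 1)) diff_diag = -idx2;
      at(iE, iE) += scale * (-p.gamma + diff_diag);
      at(iE, iJ) += scale * (p.gamma * p.kact_eig * dh1);
      at(iJ, iE) += scale * (p.gamma * p.kact_jnk * dg2 / A);
      at(iJ, iJ) += scale * (-p.gamma * p.kdeg_jnk);
      at(iJ, iS) += scale * (-p.gamma * p.kact_jnk * g2 * dA / (A * A));
      if (mutual)
        at(iS, iJ) += scale * (-p.gamma * p.kact_jak * U * h3 * dB / (B * B));
      at(iS, iS) += scale * (p.gamma * (-p.kdeg_jak + p.kact_jak * U * dh3 / B));
      at(iS, iU) += scale * (p.gamma * p.kact_jak * h3 / B);
      at(iU, iJ) += scale * (p.gamma * p.kact_upd * dh4);
      at(iU, iU) += scale * (-p.gamma * p.kdeg_upd + p.d * diff_diag);
      // diffusion off-diagonals (EIG and UPD only)
      if (i > 0) {
        at(iE, iE - 4) += scale * idx2;
        at(iU, iU - 4) += scale * p.d * idx2;
      }
      if (i < N - 1) {
        at(iE, iE + 4) += scale * idx2;
        at(iU, iU + 4) += scale * p.d * idx2;
      }
      at(iE, iE) += diag_shift;
      at(iJ, iJ) += diag_shift;
      at(iS, iS) += diag_shift;
      at(iU, iU) += diag_shift;
    }
  }
};

// Factor + solve banded system in place; returns LAPACK info.
int band_solve(std::vector<double>& AB, std::vector<int>& ipiv,
               double* b, int n) {
  const int kl = 4, ku = 4, ldab = 2 * kl + ku + 1, nrhs = 1, ldb = n;
  int info = 0;
  F77_CALL(dgbtrf)(&n, &n, &kl, &ku, AB.data(), &ldab, ipiv.data(), &info);
  if (info != 0) return info;
  F77_CALL(dgbtrs)("N", &n, &kl, &ku, &nrhs, AB.data(), &ldab, ipiv.data(),
                   b, &ldb, &info FCONE);
  return info;
}

double max_abs(const std::vector<double>& v) {
  double m = 0.0;
  for (double x : v) { double a = std::fabs(x); if (a > m) m = a; }
  return m;
}

} // namespace

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector state, NumericVector q,
                      NumericVector wound, bool mutual, int boundary) {
  Model m(q, wound, mutual, boundary);
  if (state.size() != m.n()) stop("state length must be 4 * compartments");
  NumericVector out(m.n());
  m.rhs(REAL(state), REAL(out));
  return out;
}

// Adaptive implicit-Euler integration to steady state with a
// trapezoidal-comparison local error estimate.
// [[Rcpp::export(name = ".integrate_cpp")]]
List integrate_cpp(NumericVector q, NumericVector wound, bool mutual,
                   int boundary, NumericVector init, double t_max,
                   double ss_tol, double rtol, double atol, int max_steps,
                   NumericVector frame_times) {
  Model m(q, wound, mutual, boundary);
  const int n = m.n();
  if (init.size() != n) stop("initial state length must be 4 * compartments");
  std::vector<double> u(init.begin(), init.end());
  std::vector<double> f(n), fv(n), v(n), res(n), u_prev(n);
  std::vector<double> AB((size_t)13 * n);
  std::vector<int> ipiv(n);

  const int n_frames = frame_times.size();
  NumericMatrix kymo(n_frames > 0 ? n_frames : 0, n_frames > 0 ? n : 0);
  int next_frame = 0;
  auto record_upto = [&](double t0, double t1, const std::vector<double>& a,
                         const std::vector<double>& b) {
    while (next_frame < n_frames && frame_times[next_frame] <= t1) {
      double ft = frame_times[next_frame];
      double w = (t1 > t0) ? (ft - t0) / (t1 - t0) : 1.0;
      for (int j = 0; j < n; ++j)
        kymo(next_frame, j) = (1.0 - w) * a[j] + w * b[j];
      ++next_frame;
    }
  };
  if (n_frames > 0) record_upto(0.0, 0.0, u, u);

  double t = 0.0, dt = 1e-4;
  bool converged = false;
  int steps = 0;
  std::string diag = "ok";
  double traj_min = 0.0;  // most negative entry seen along the trajectory
  for (int j = 0; j < n; ++j) if (u[j] < traj_min) traj_min = u[j];

  m.rhs(u.data(), f.data());
  double resid = max_abs(f);
  if (resid < ss_tol) converged = true;

  while (!converged && t < t_max) {
    if (++steps > max_steps) { diag = "max_steps"; break; }
    if (dt > t_max - t) dt = t_max - t;

    // Chord-Newton solve for v: v - u - dt f(v) = 0, predictor
    // v = u + dt f(u); the iteration matrix (I - dt J) is factorized at
    // the predictor and reused, refactorized mid-iteration if needed.
    for (int j = 0; j < n; ++j) v[j] = pos(u[j] + dt * f[j]);
    bool newton_ok = false;
    bool factored = false;
    for (int it = 0; it < 12; ++it) {
      m.rhs(v.data(), fv.data());
      double rmax = 0.0;
      for (int j = 0; j < n; ++j) {
        res[j] = v[j] - u[j] - dt * fv[j];
        double sc = atol + rtol * std::fabs(v[j]);
        double r = std::fabs(res[j]) / sc;
        if (r > rmax) rmax = r;
      }
      if (rmax < 1e-4) { newton_ok = true; break; }
      if (!factored || it == 4 || it == 8) {
        m.jac_banded(v.data(), AB.data(), 1.0, -dt);
        const int kl = 4, ku = 4, ldab = 13;
        int info = 0;
        F77_CALL(dgbtrf)(&n, &n, &kl, &ku, AB.data(), &ldab, ipiv.data(), &info);
        if (info != 0) break;
        factored = true;
      }
      {
        const int kl = 4, ku = 4, ldab = 13, nrhs = 1;
        int info = 0;
        F77_CALL(dgbtrs)("N", &n, &kl, &ku, &nrhs, AB.data(), &ldab,
                         ipiv.data(), res.data(), &n, &info FCONE);
        if (info != 0) break;
      }
      bool finite = true;
      for (int j = 0; j < n; ++j) {
        v[j] -= res[j];
        if (!R_finite(v[j])) { finite = false; break; }
      }
      if (!finite) break;
    }
    if (!newton_ok) { dt *= 0.25; if (dt < 1e-14) { diag = "step_collapse"; break; } continue; }

    // local error: implicit Euler vs trapezoidal completion
    double err = 0.0;
    for (int j = 0; j < n; ++j) {
      double tr = u[j] + 0.5 * dt * (f[j] + fv[j]);
      double sc = atol + rtol * std::max(std::fabs(u[j]), std::fabs(v[j]));
      double e = std::fabs(v[j] - tr) / sc;
      if (e > err) err = e;
    }
    double fac = 0.9 / std::sqrt(err + 1e-10);
    if (fac > 3.0) fac = 3.0;
    if (fac < 0.2) fac = 0.2;
    if (err > 1.0) { dt *= fac; continue; }

    // accept
    double bad = 0.0;
    for (int j = 0; j < n; ++j) {
      if (v[j] < 0.0) {
        if (v[j] < bad) bad = v[j];
        if (v[j] > -1e-9) v[j] = 0.0;
      }
    }
    if (bad < -1e-9) { dt *= 0.25; continue; }
    u_prev = u;
    u = v;
    for (int j = 0; j < n; ++j) if (u[j] < traj_min) traj_min = u[j];
    double t_new = t + dt;
    if (n_frames > 0) record_upto(t, t_new, u_prev, u);
    t = t_new;
    dt *= fac;
    m.rhs(u.data(), f.data());
    resid = max_abs(f);
    if (resid < ss_tol) { converged = true; break; }
  }
  // Newton polish of a detected steady state: the residual tolerance on
  // max|du/dt| bounds the state error only up to the local Jacobian scale,
  // so quench the root to ~1e-10 before reporting.
  if (converged) {
    for (int it = 0; it < 8 && resid > 1e-10; ++it) {
      res = f;
      m.jac_banded(u.data(), AB.data(), 0.0, 1.0);
      if (band_solve(AB, ipiv, res.data(), n) != 0) break;
      bool finite = true;
      // newton step: u_new = u - J^{-1} f  (res holds J^{-1} f)
      for (int j = 0; j < n; ++j) {
        v[j] = u[j] - res[j];
        if (!R_finite(v[j])) { finite = false; break; }
        if (v[j] < 0.0 && v[j] > -1e-9) v[j] = 0.0;
      }
      if (!finite) break;
      m.rhs(v.data(), fv.data());
      double rnew = max_abs(fv);
      if (!R_finite(rnew) || rnew >= resid) break;
      u = v; f = fv; resid = rnew;
    }
  }
  if (n_frames > 0) {  // pad remaining frames with the final state
    while (next_frame < n_frames) {
      for (int j = 0; j < n; ++j) kymo(next_frame, j) = u[j];
      ++next_frame;
    }
  }
  List out = List::create(
    _["state"] = NumericVector(u.begin(), u.end()),
    _["t"] = t, _["residual"] = resid, _["converged"] = converged,
    _["steps"] = steps, _["diag"] = diag, _["traj_min"] = traj_min);
  if (n_frames > 0) out["kymograph"] = kymo;
  return out;
}

// Damped Newton root-finder for rhs(u) = 0.
// [[Rcpp::export(name = ".newton_cpp")]]
List newton_cpp(NumericVector q, NumericVector wound, bool mutual,
                int boundary, NumericVector guess, double tol,
                int max_iter) {
  Model m(q, wound, mutual, boundary);
  const int n = m.n();
  if (guess.size() != n) stop("guess length must be 4 * compartments");
  std::vector<double> u(guess.begin(), guess.end());
  std::vector<double> f(n), step(n), trial(n), ftrial(n);
  std::vector<double> AB((size_t)13 * n);
  std::vector<int> ipiv(n);
  m.rhs(u.data(), f.data());
  double fnorm = max_abs(f);
  bool converged = fnorm <= tol;
  std::string diag = "ok";
  int it = 0;
  while (!converged && it < max_iter) {
    ++it;
    step = f;
    m.jac_banded(u.data(), AB.data(), 0.0, 1.0);
    if (band_solve(AB, ipiv, step.data(), n) != 0) {
      diag = "singular_jacobian";
      break;
    }
    // step at machine precision: the iterate is a root to double
    // precision even if the absolute residual floor (~ O(J) * eps)
    // sits above tol for large-rate parameter sets
    double snorm = max_abs(step);
    double unorm = 0.0;
    for (int j = 0; j < n; ++j)
      if (std::fabs(u[j]) > unorm) unorm = std::fabs(u[j]);
    if (snorm <= 1e-12 * (1.0 + unorm)) {
      converged = true;
      diag = "step_floor";
      break;
    }
    double lambda = 1.0;
    bool accepted = false;
    for (int ls = 0; ls < 25; ++ls) {
      bool finite = true;
      for (int j = 0; j < n; ++j) {
        trial[j] = u[j] - lambda * step[j];
        if (!R_finite(trial[j])) { finite = false; break; }
      }
      if (finite) {
        m.rhs(trial.data(), ftrial.data());
        double fn = max_abs(ftrial);
        if (R_finite(fn) && fn < fnorm * (1.0 - 1e-4 * lambda) + 1e-300) {
          u = trial; f = ftrial; fnorm = fn; accepted = true;
          break;
        }
      }
      lambda *= 0.5;
    }
    if (!accepted) {
      // stagnation with a tiny proposed step is the same machine floor
      if (snorm <= 1e-9 * (1.0 + unorm)) {
        converged = true;
        diag = "step_floor";
      } else {
        diag = "line_search_failed";
      }
      break;
    }
    if (fnorm <= tol) converged = true;
  }
  return List::create(
    _["state"] = NumericVector(u.begin(), u.end()),
    _["residual"] = fnorm, _["converged"] = converged,
    _["iterations"] = it, _["diag"] = diag);
}
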