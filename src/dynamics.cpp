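#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Euler-Maruyama integrators for the SC-coupled regional dynamics. All
// stochastic draws go through R's RNG so that set.seed() in R fully
// determines every trajectory. `C` is the effective coupling matrix
// (global coupling already folded in, typically G * row-normalised SC).

static inline void matvec(const NumericMatrix& C, const std::vector<double>& x,
                          std::vector<double>& out) {
  int n = C.nrow();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += C(i, j) * x[j];
    out[i] = s;
  }
}

static void check_finite(const std::vector<double>& x, int step, double dt) {
  for (size_t i = 0; i < x.size(); ++i) {
    if (!std::isfinite(x[i]))
      stop("state diverged (non-finite value) at t = %f s", step * dt);
  }
}

// Linear rate model: tau dx = (-x + C x) dt + tau * sigma dW
// [[Rcpp::export(name = ".sim_rate_cpp")]]
NumericMatrix sim_rate_cpp(NumericMatrix C, double tau, double noise_sd,
                           double dt, int burn_steps, int n_samples,
                           int sample_every) {
  int n = C.nrow();
  std::vector<double> x(n), cx(n);
  for (int i = 0; i < n; ++i) x[i] = 0.1 * R::norm_rand();
  NumericMatrix out(n, n_samples);
  double sq = noise_sd * std::sqrt(dt);
  int total = burn_steps + n_samples * sample_every;
  int kept = 0;
  for (int s = 1; s <= total; ++s) {
    matvec(C, x, cx);
    for (int i = 0; i < n; ++i)
      x[i] += (-x[i] + cx[i]) * dt / tau + sq * R::norm_rand();
    if (s % 100000 == 0) check_finite(x, s, dt);
    if (s > burn_steps && (s - burn_steps) % sample_every == 0) {
      for (int i = 0; i < n; ++i) out(i, kept) = x[i];
      ++kept;
    }
  }
  check_finite(x, total, dt);
  return out;
}

// Kuramoto phase oscillators; the observable is sin(theta).
// dtheta_i = omega_i dt + sum_j C_ij sin(theta_j - theta_i) dt + sigma dW
// [[Rcpp::export(name = ".sim_kuramoto_cpp")]]
NumericMatrix sim_kuramoto_cpp(NumericMatrix C, NumericVector omega,
                               double noise_sd, double dt, int burn_steps,
                               int n_samples, int sample_every) {
  int n = C.nrow();
  std::vector<double> th(n), st(n), ct(n), cs(n), cc(n);
  for (int i = 0; i < n; ++i) th[i] = R::unif_rand() * 2.0 * M_PI;
  NumericMatrix out(n, n_samples);
  double sq = noise_sd * std::sqrt(dt);
  int total = burn_steps + n_samples * sample_every;
  int kept = 0;
  for (int s = 1; s <= total; ++s) {
    for (int i = 0; i < n; ++i) { st[i] = std::sin(th[i]); ct[i] = std::cos(th[i]); }
    matvec(C, st, cs);
    matvec(C, ct, cc);
    for (int i = 0; i < n; ++i) {
      // sum_j C_ij sin(th_j - th_i) = cos(th_i) (C sin th)_i - sin(th_i) (C cos th)_i
      th[i] += (omega[i] + ct[i] * cs[i] - st[i] * cc[i]) * dt + sq * R::norm_rand();
    }
    if (s > burn_steps && (s - burn_steps) % sample_every == 0) {
      for (int i = 0; i < n; ++i) out(i, kept) = std::sin(th[i]);
      ++kept;
    }
  }
  check_finite(th, total, dt);
  return out;
}

static inline double sigm(double x, double a, double th) {
  return 1.0 / (1.0 + std::exp(-a * (x - th)));
}

// Wilson-Cowan excitatory/inhibitory pair per region; observable is E.
// par = (c1, c2, c3, c4, a_e, th_e, a_i, th_i, P, Q, tau)
// [[Rcpp::export(name = ".sim_wilson_cowan_cpp")]]
NumericMatrix sim_wilson_cowan_cpp(NumericMatrix C, NumericVector par,
                                   double noise_sd, double dt, int burn_steps,
                                   int n_samples, int sample_every) {
  int n = C.nrow();
  double c1 = par[0], c2 = par[1], c3 = par[2], c4 = par[3];
  double ae = par[4], the = par[5], ai = par[6], thi = par[7];
  double P = par[8], Q = par[9], tau = par[10];
  std::vector<double> E(n), I(n), cE(n);
  for (int i = 0; i < n; ++i) {
    E[i] = 0.1 + 0.05 * R::norm_rand();
    I[i] = 0.1 + 0.05 * R::norm_rand();
  }
  NumericMatrix out(n, n_samples);
  double sq = noise_sd * std::sqrt(dt);
  int total = burn_steps + n_samples * sample_every;
  int kept = 0;
  for (int s = 1; s <= total; ++s) {
    matvec(C, E, cE);
    for (int i = 0; i < n; ++i) {
      double dE = (-E[i] + sigm(c1 * E[i] - c2 * I[i] + cE[i] + P, ae, the)) / tau;
      double dI = (-I[i] + sigm(c3 * E[i] - c4 * I[i] + Q, ai, thi)) / tau;
      E[i] += dE * dt + sq * R::norm_rand();
      I[i] += dI * dt + sq * R::norm_rand();
    }
    if (s % 100000 == 0) check_finite(E, s, dt);
    if (s > burn_steps && (s - burn_steps) % sample_every == 0) {
      for (int i = 0; i < n; ++i) out(i, kept) = E[i];
      ++kept;
    }
  }
  check_finite(E, total, dt);
  return out;
}

// FitzHugh-Nagumo fast-slow pair per region; observable is the fast variable.
// par = (a, b, phi, I_ext, tau) with tau the time scale in seconds of one
// model time unit.
// [[Rcpp::export(name = ".sim_fhn_cpp")]]
NumericMatrix sim_fhn_cpp(NumericMatrix C, NumericVector par, double noise_sd,
                          double dt, int burn_steps, int n_samples,
                          int sample_every) {
  int n = C.nrow();
  double a = par[0], b = par[1], phi = par[2], Iext = par[3], tau = par[4];
  std::vector<double> v(n), w(n), cv(n);
  for (int i = 0; i < n; ++i) {
    v[i] = 0.5 * R::norm_rand();
    w[i] = 0.1 * R::norm_rand();
  }
  NumericMatrix out(n, n_samples);
  double sq = noise_sd * std::sqrt(dt);
  int total = burn_steps + n_samples * sample_every;
  int kept = 0;
  for (int s = 1; s <= total; ++s) {
    matvec(C, v, cv);
    for (int i = 0; i < n; ++i) {
      double dv = (v[i] - v[i] * v[i] * v[i] / 3.0 - w[i] + Iext + cv[i]) / tau;
      double dw = phi * (v[i] + a - b * w[i]) / tau;
      v[i] += dv * dt + sq * R::norm_rand();
      w[i] += dw * dt;
    }
    if (s % 100000 == 0) check_finite(v, s, dt);
    if (s > burn_steps && (s - burn_steps) % sample_every == 0) {
      for (int i = 0; i < n; ++i) out(i, kept) = v[i];
      ++kept;
    }
  }
  check_finite(v, total, dt);
  return out;
}

// Balloon-Windkessel hemodynamics, one independent 4-state system per
// region (vasodilatory signal s, inflow f, venous volume v, deoxyhemoglobin
// q), driven by the neural observable (held constant across substeps within
// one neural sample) and integrated by Euler with `substeps` internal steps
// per neural sample. Returns percent-signal-change BOLD on the neural grid.
// par = (kappa, gamma, tau, alpha, E0, V0)
// [[Rcpp::export(name = ".balloon_windkessel_cpp")]]
NumericMatrix balloon_windkessel_cpp(NumericMatrix neural, double dt,
                                     NumericVector par, int substeps) {
  int n = neural.nrow(), T = neural.ncol();
  if (substeps < 1) stop("substeps must be >= 1");
  double kappa = par[0], gamma = par[1], tau = par[2], alpha = par[3];
  double E0 = par[4], V0 = par[5];
  double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  double ia = 1.0 / alpha;
  double h = dt / substeps;
  NumericMatrix out(n, T);
  for (int i = 0; i < n; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      double z = neural(i, t);
      for (int ss = 0; ss < substeps; ++ss) {
        double ds = z - kappa * s - gamma * (f - 1.0);
        double df = s;
        double fv = std::pow(v, ia);
        double Ef = 1.0 - std::pow(1.0 - E0, 1.0 / f);
        double dv = (f - fv) / tau;
        double dq = (f * Ef / E0 - fv * q / v) / tau;
        s += ds * h;
        f += df * h;
        v += dv * h;
        q += dq * h;
        if (f < 1e-4) f = 1e-4;  // guard against unphysical reversal of flow
        if (v < 1e-4) v = 1e-4;
        if (q < 1e-6) q = 1e-6;
      }
      if (!std::isfinite(s) || !std::isfinite(v) || !std::isfinite(q))
        stop("hemodynamic state diverged at t = %f s (region %d)", t * dt, i + 1);
      out(i, t) = 100.0 * V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
  }
  return out;
}
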