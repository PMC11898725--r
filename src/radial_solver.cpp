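#include <Rcpp.h>
using namespace Rcpp;

// Backward-Euler finite-volume march for radial conduction in a porous
// sphere with a temperature-dependent metabolic source.
//
// Cells i = 1..n with faces at r_j = j*dr, centers at (i - 1/2)*dr.
// Per step the nonlinearities (k_eff, Cp, source) are evaluated at the
// previous-step temperatures, giving one tridiagonal solve per step.
// The Robin surface condition enters as a series resistance
// 1/h + dr/(2 k_n) on the outer face, which keeps the scheme
// flux-conservative: the discrete energy audit is exact up to round-off.

static inline double mix_k(double ks, double kf, double phi, int rule) {
  switch (rule) {
    case 1:  return 1.0 / ((1.0 - phi) / ks + phi / kf);   // harmonic
    case 2:  return std::pow(ks, 1.0 - phi) * std::pow(kf, phi); // geometric
    default: return (1.0 - phi) * ks + phi * kf;           // arithmetic
  }
}

// [[Rcpp::export(name = ".radial_solve_cpp")]]
List radial_solve_cpp(double R, int n, double dt, double t_end, double out_dt,
                      NumericVector k_coeffs, NumericVector cp_coeffs,
                      double rho_s, double phi, double rho_f, double cp_f,
                      double k_f, int mix_rule,
                      double h, double T_inf, double T0,
                      int src_type, double qdot_const,
                      double resp_c, double resp_g, bool resp_literal,
                      double resp_density) {
  if (n < 2) stop("n_nodes must be at least 2");
  if (dt <= 0.0 || t_end <= 0.0) stop("dt and t_end must be positive");
  const double pi = M_PI;
  const double dr = R / n;

  std::vector<double> V(n), Aface(n + 1), rc(n);
  for (int j = 0; j <= n; ++j) {
    double rj = j * dr;
    Aface[j] = 4.0 * pi * rj * rj;
  }
  double Vtot = 0.0;
  for (int i = 0; i < n; ++i) {
    double r0 = i * dr, r1 = (i + 1) * dr;
    V[i] = 4.0 / 3.0 * pi * (r1 * r1 * r1 - r0 * r0 * r0);
    rc[i] = (i + 0.5) * dr;
    Vtot += V[i];
  }

  int n_steps = (int)std::ceil(t_end / dt - 1e-12);
  int stride = std::max(1, (int)std::lround(out_dt / dt));
  int n_out = n_steps / stride + 1;

  NumericVector T(n, T0), Tnew(n);
  NumericMatrix temps(n, n_out);
  NumericVector times(n_out), vavg(n_out), surface(n_out), center(n_out);
  NumericVector e_stored(n_out), e_supplied(n_out);

  std::vector<double> keff(n), C(n), q(n), G(n + 1);
  std::vector<double> a(n), b(n), c(n), d(n), cp(n), dp(n);

  double stored = 0.0, supplied = 0.0;
  int io = 0;
  // record initial state
  for (int i = 0; i < n; ++i) temps(i, 0) = T[i];
  times[0] = 0.0;
  { double s = 0.0; for (int i = 0; i < n; ++i) s += V[i] * T[i];
    vavg[0] = s / Vtot; }
  surface[0] = T0; center[0] = T0;
  e_stored[0] = 0.0; e_supplied[0] = 0.0;
  io = 1;

  for (int step = 1; step <= n_steps; ++step) {
    // lagged property and source evaluation
    for (int i = 0; i < n; ++i) {
      double Ti = T[i];
      double ks = k_coeffs[0] + k_coeffs[1] * Ti;
      double cps = cp_coeffs[0] + cp_coeffs[1] * Ti + cp_coeffs[2] * Ti * Ti;
      keff[i] = mix_k(ks, k_f, phi, mix_rule);
      C[i] = (1.0 - phi) * rho_s * cps + phi * rho_f * cp_f;
      if (src_type == 1) {
        q[i] = qdot_const;
      } else if (src_type == 2) {
        double base = resp_literal ? 9.0 * Ti + 32.0 : 9.0 * Ti / 5.0 + 32.0;
        if (base <= 0.0) stop("respiration source outside model domain");
        q[i] = resp_c * std::pow(base, resp_g) * resp_density;
      } else {
        q[i] = 0.0;
      }
      if (!std::isfinite(keff[i]) || keff[i] <= 0.0 || C[i] <= 0.0)
        stop("non-physical property value during march");
    }
    // face conductances
    G[0] = 0.0;                                   // symmetry at r = 0
    for (int j = 1; j < n; ++j)
      G[j] = 0.5 * (keff[j - 1] + keff[j]) * Aface[j] / dr;
    G[n] = Aface[n] / (1.0 / h + dr / (2.0 * keff[n - 1]));

    // assemble tridiagonal system
    for (int i = 0; i < n; ++i) {
      double m = C[i] * V[i] / dt;
      a[i] = (i > 0) ? -G[i] : 0.0;
      c[i] = (i < n - 1) ? -G[i + 1] : 0.0;
      b[i] = m + G[i] + G[i + 1] * ((i < n - 1) ? 1.0 : 0.0);
      d[i] = m * T[i] + q[i] * V[i];
      if (i == n - 1) { b[i] += G[n]; d[i] += G[n] * T_inf; }
    }
    // Thomas algorithm
    cp[0] = c[0] / b[0];
    dp[0] = d[0] / b[0];
    for (int i = 1; i < n; ++i) {
      double denom = b[i] - a[i] * cp[i - 1];
      cp[i] = c[i] / denom;
      dp[i] = (d[i] - a[i] * dp[i - 1]) / denom;
    }
    Tnew[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) Tnew[i] = dp[i] - cp[i] * Tnew[i + 1];

    // energy audit with the same discrete quantities
    double flux_in = G[n] * (T_inf - Tnew[n - 1]);
    double src_in = 0.0, dstore = 0.0;
    for (int i = 0; i < n; ++i) {
      src_in += q[i] * V[i];
      dstore += C[i] * V[i] * (Tnew[i] - T[i]);
      if (!std::isfinite(Tnew[i]))
        stop("solver diverged (non-finite temperature) at step %d", step);
    }
    stored += dstore;
    supplied += dt * (flux_in + src_in);
    for (int i = 0; i < n; ++i) T[i] = Tnew[i];

    if (step % stride == 0 && io < n_out) {
      times[io] = step * dt;
      double s = 0.0;
      for (int i = 0; i < n; ++i) { temps(i, io) = T[i]; s += V[i] * T[i]; }
      vavg[io] = s / Vtot;
      surface[io] = T_inf + G[n] * (T[n - 1] - T_inf) / (h * Aface[n]);
      center[io] = T[0];
      e_stored[io] = stored;
      e_supplied[io] = supplied;
      ++io;
    }
  }

  NumericVector radii(n);
  for (int i = 0; i < n; ++i) radii[i] = rc[i];
  return List::create(_["node_radii"] = radii, _["times"] = times,
                      _["temperatures"] = temps, _["volume_average"] = vavg,
                      _["surface"] = surface, _["center"] = center,
                      _["energy_stored"] = e_stored,
                      _["energy_supplied"] = e_supplied);
}
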