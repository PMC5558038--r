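#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of a symmetric two-bound diffusion with unit
// variance per second.  The bound may vary over time (length n_steps + 1,
// values at the step edges).  Crossings inside a step are detected with a
// Brownian-bridge correction: conditional on the endpoints the probability
// that the path touched a (locally linearized) bound within the step is
// exp(-2 d0 d1 / dt), with d0, d1 the start/end distances to the bound.
// drift_off gives, per trial, the step index after which the drift is zero
// (set to n_steps for a drift that never switches off).
// [[Rcpp::export]]
List cpp_sim_ddm(NumericVector drift, IntegerVector drift_off,
                 NumericVector bound, double dt, int n_steps) {
  int n = drift.size();
  NumericVector dtime(n, NA_REAL);
  IntegerVector choice(n, NA_INTEGER);
  LogicalVector terminated(n);
  NumericVector xfinal(n);
  double sdt = std::sqrt(dt);

  for (int i = 0; i < n; ++i) {
    double x = 0.0;
    bool done = false;
    for (int k = 0; k < n_steps; ++k) {
      double mu = (k < drift_off[i]) ? drift[i] : 0.0;
      double xn = x + mu * dt + sdt * norm_rand();
      double b0 = bound[k], b1 = bound[k + 1];
      double t_mid = (k + 0.5) * dt;
      if (xn >= b1) {
        choice[i] = 1; dtime[i] = t_mid; done = true;
      } else if (xn <= -b1) {
        choice[i] = 0; dtime[i] = t_mid; done = true;
      } else {
        // bridge crossing probabilities for upper and lower bound
        double du0 = b0 - x, du1 = b1 - xn;
        double dl0 = b0 + x, dl1 = b1 + xn;
        double pu = (du0 > 0 && du1 > 0) ? std::exp(-2.0 * du0 * du1 / dt) : 1.0;
        double pl = (dl0 > 0 && dl1 > 0) ? std::exp(-2.0 * dl0 * dl1 / dt) : 1.0;
        double u = unif_rand();
        if (u < pu) {
          choice[i] = 1; dtime[i] = t_mid; done = true;
        } else if (u < pu + pl) {
          choice[i] = 0; dtime[i] = t_mid; done = true;
        }
      }
      if (done) { terminated[i] = true; xfinal[i] = xn; break; }
      x = xn;
    }
    if (!done) { terminated[i] = false; xfinal[i] = x; }
  }
  return List::create(_["choice"] = choice, _["decision_time"] = dtime,
                      _["terminated"] = terminated, _["x_final"] = xfinal);
}

// Thomas algorithm for the constant-coefficient tridiagonal system
// (a, b, c) of size m; solves into d using scratch buffers cp, dp.
static void solve_tridiag_const(double a, double b, double c, double* d,
                                int m, double* cp, double* dp) {
  if (m == 0) return;
  cp[0] = c / b;
  dp[0] = d[0] / b;
  for (int i = 1; i < m; ++i) {
    double w = b - a * cp[i - 1];
    cp[i] = c / w;
    dp[i] = (d[i] - a * dp[i - 1]) / w;
  }
  d[m - 1] = dp[m - 1];
  for (int i = m - 2; i >= 0; --i) d[i] = dp[i] - cp[i] * d[i + 1];
}

// First-passage-time density of a constant-drift, unit-variance diffusion
// between symmetric absorbing bounds +/- bound(t), by Crank-Nicolson
// propagation of the transition density on a fixed space grid.  The first
// steps use backward-Euler substeps (Rannacher smoothing) to damp the
// oscillations a delta initial condition induces in Crank-Nicolson.
// bound has length n_steps + 1 (values at step edges).  Mass absorbed in
// step k is recorded at bin center (k + 0.5) * dt; attribution to the upper
// or lower bound follows the diffusive flux at the respective edge.
// [[Rcpp::export]]
List cpp_fpt_density(double drift, NumericVector bound, double dt, double dx,
                     double A0, int n_steps) {
  int half = (int) std::round(A0 / dx);
  if (half < 2) stop("dx too coarse for the bound height");
  int nx = 2 * half + 1;           // x_j = (j - half) * dx
  std::vector<double> p(nx, 0.0);
  p[half] = 1.0 / dx;              // delta at zero
  NumericVector dens_up(n_steps), dens_lo(n_steps);
  double abs_up = 0.0, abs_lo = 0.0;

  // L p = 0.5 p_xx - mu p_x.  Crank-Nicolson: (I - dt/2 L) p' = (I + dt/2 L) p.
  // With r = dt/(4 dx^2), q = mu dt/(4 dx) the half-operator dt/2 L has
  // coefficients (r + q, -2r, r - q) on (p_{j-1}, p_j, p_{j+1}).
  double r = dt / (4.0 * dx * dx);
  double q = drift * dt / (4.0 * dx);
  std::vector<double> rhs(nx), cp(nx), dp(nx);

  for (int k = 0; k < n_steps; ++k) {
    double b_new = bound[k + 1];
    double lost_up = 0.0, lost_lo = 0.0;

    // absorb cells swept by the collapsing bound (position beyond the bound)
    for (int j = 0; j < nx; ++j) {
      if (p[j] <= 0.0) continue;
      double x = (j - half) * dx;
      if (x >= b_new - 1e-12 && x > 0) { lost_up += p[j] * dx; p[j] = 0.0; }
      else if (x <= -b_new + 1e-12 && x < 0) { lost_lo += p[j] * dx; p[j] = 0.0; }
      else if (std::fabs(x) < 1e-12 && b_new <= dx * 0.5) {
        lost_up += 0.5 * p[j] * dx; lost_lo += 0.5 * p[j] * dx; p[j] = 0.0;
      }
    }

    // active interior nodes strictly inside the bound
    int jlo = half - (int) std::floor((b_new - 1e-12) / dx);
    int jhi = half + (int) std::floor((b_new - 1e-12) / dx);
    if (jlo < 1) jlo = 1;
    if (jhi > nx - 2) jhi = nx - 2;
    int m = jhi - jlo + 1;

    if (m > 0) {
      double mass_before = 0.0;
      for (int j = jlo; j <= jhi; ++j) mass_before += p[j];
      mass_before *= dx;

      const double lo_c = -(r + q), di_c = 1.0 + 2.0 * r, up_c = -(r - q);
      if (k < 2) {
        // two backward-Euler substeps of dt/2 each (Rannacher smoothing);
        // the implicit matrix I - (dt/2) L is the same as Crank-Nicolson's
        for (int sub = 0; sub < 2; ++sub) {
          for (int i = 0; i < m; ++i) rhs[i] = p[jlo + i];
          solve_tridiag_const(lo_c, di_c, up_c, rhs.data(), m, cp.data(),
                              dp.data());
          for (int i = 0; i < m; ++i) p[jlo + i] = std::max(rhs[i], 0.0);
        }
      } else {
        // Crank-Nicolson step: (I - dt/2 L) p_new = (I + dt/2 L) p_old
        for (int i = 0; i < m; ++i) {
          double pm = (i > 0) ? p[jlo + i - 1] : 0.0;
          double pp = (i < m - 1) ? p[jlo + i + 1] : 0.0;
          rhs[i] = p[jlo + i] * (1.0 - 2.0 * r) + pm * (r + q) + pp * (r - q);
        }
        solve_tridiag_const(lo_c, di_c, up_c, rhs.data(), m, cp.data(),
                            dp.data());
        for (int i = 0; i < m; ++i) p[jlo + i] = std::max(rhs[i], 0.0);
      }

      double mass_after = 0.0;
      for (int j = jlo; j <= jhi; ++j) mass_after += p[j];
      mass_after *= dx;
      double lost = mass_before - mass_after;
      if (lost > 0) {
        double w_up = p[jhi] + 1e-300, w_lo = p[jlo] + 1e-300;
        if (drift > 0) w_up += 1e-30; else if (drift < 0) w_lo += 1e-30;
        lost_up += lost * w_up / (w_up + w_lo);
        lost_lo += lost * w_lo / (w_up + w_lo);
      }
    } else {
      // bound collapsed below one cell: everything already swept above
    }

    dens_up[k] = lost_up / dt;
    dens_lo[k] = lost_lo / dt;
    abs_up += lost_up;
    abs_lo += lost_lo;
  }

  double survival = 0.0;
  for (int j = 0; j < nx; ++j) survival += p[j];
  survival *= dx;
  return List::create(_["density_right"] = dens_up, _["density_left"] = dens_lo,
                      _["p_right"] = abs_up, _["p_left"] = abs_lo,
                      _["survival"] = survival);
}
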