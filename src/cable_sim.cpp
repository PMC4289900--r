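#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Implicit integration of the branched cable equation with a single
// first-order HCN gate per segment.
//
// Units: pA, mV, nS, pF, ms. The segment tree must be ordered so that
// parent[i] < i (0-based; parent[0] == -1 for the root). The per-step linear
// system is solved exactly by ordered (Hines) elimination on the tree.
//
// theta = 0.5 gives the trapezoid (Crank-Nicolson) scheme with the gate
// advanced by the locally exact exponential (Rush-Larsen) rule; theta = 1 is
// backward Euler.
//
// stim: (nsteps+1) x nstim matrix of injected currents sampled at step
// boundaries; the current over a step is taken at the step midpoint.
// [[Rcpp::export(name = ".simulate_cable_cpp")]]
NumericMatrix simulate_cable_cpp(IntegerVector parent,
                                 NumericVector cap_pF,
                                 NumericVector g_leak,
                                 NumericVector e_leak,
                                 NumericVector gh_max,
                                 double e_h,
                                 NumericVector g_axial,
                                 double v_half, double k_slope,
                                 double tau_peak, double tau_vmid,
                                 double tau_width, double q_factor,
                                 double dt, int nsteps, double v_init,
                                 IntegerVector stim_sites,
                                 NumericMatrix stim,
                                 IntegerVector record_sites,
                                 double theta) {
  const int n = parent.size();
  const int nrec = record_sites.size();
  const int nstim = stim_sites.size();
  if (nstim > 0 && stim.nrow() != nsteps + 1)
    stop("stimulus must have nsteps+1 rows");

  const int* par = INTEGER(parent);
  const double* gl = REAL(g_leak);
  const double* el = REAL(e_leak);
  const double* gh = REAL(gh_max);
  const double* gax = REAL(g_axial);

  std::vector<double> v(n, v_init), m(n, 0.0);
  std::vector<double> d(n), rhs(n), f(n);
  std::vector<double> cdt(n), gsum(n), offd0(n), bstat(n), ghm(n);

  bool has_h = false;
  for (int i = 0; i < n; ++i) if (gh[i] > 0) { has_h = true; break; }

  for (int i = 0; i < n; ++i) {
    cdt[i] = cap_pF[i] / dt;
    gsum[i] = gax[i];
    offd0[i] = -theta * gax[i];
    bstat[i] = gl[i] * el[i];
  }
  for (int i = 1; i < n; ++i) gsum[par[i]] += gax[i];

  const double m0 = 1.0 / (1.0 + std::exp((v_init - v_half) / k_slope));
  for (int i = 0; i < n; ++i) { m[i] = m0; ghm[i] = gh[i] * m0; }

  NumericMatrix out(nsteps + 1, nrec);
  for (int r = 0; r < nrec; ++r) out(0, r) = v[record_sites[r]];
  const double w = 1.0 - theta;

  for (int step = 0; step < nsteps; ++step) {
    if (has_h) {
      // Rush-Larsen gate update using V at the step start
      for (int i = 0; i < n; ++i) {
        if (gh[i] <= 0) continue;
        const double vi = v[i];
        const double minf = 1.0 / (1.0 + std::exp((vi - v_half) / k_slope));
        const double u = (vi - tau_vmid) / tau_width;
        double tau = q_factor * 2.0 * tau_peak / (std::exp(u) + std::exp(-u));
        if (tau < 1e-3) tau = 1e-3;
        m[i] = minf + (m[i] - minf) * std::exp(-dt / tau);
        ghm[i] = gh[i] * m[i];
      }
    }

    // (C/dt + theta*A) v' = (C/dt - (1-theta)*A) v + b
    for (int i = 0; i < n; ++i) {
      const double gtot = gl[i] + ghm[i] + gsum[i];
      d[i] = cdt[i] + theta * gtot;
      rhs[i] = (cdt[i] - w * gtot) * v[i] + bstat[i] + ghm[i] * e_h;
    }
    if (w > 0) {
      for (int i = 1; i < n; ++i) {
        const int p = par[i];
        const double g = w * gax[i];
        rhs[i] += g * v[p];
        rhs[p] += g * v[i];
      }
    }
    for (int s = 0; s < nstim; ++s) {
      rhs[stim_sites[s]] += 0.5 * (stim(step, s) + stim(step + 1, s));
    }

    // Hines elimination (children have larger indices than parents),
    // storing the scaled off-diagonal for the back-substitution sweep
    for (int i = n - 1; i >= 1; --i) {
      const int p = par[i];
      const double inv = 1.0 / d[i];
      const double fi = offd0[i] * inv;
      f[i] = fi;
      rhs[i] *= inv;
      d[p] -= offd0[i] * fi;
      rhs[p] -= offd0[i] * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) {
      v[i] = rhs[i] - f[i] * v[par[i]];
    }

    for (int r = 0; r < nrec; ++r) out(step + 1, r) = v[record_sites[r]];

    if ((step & 1023) == 0 && !std::isfinite(v[0])) {
      stop("numerical error: non-finite voltage at t = %f ms",
           (step + 1) * dt);
    }
  }
  if (!std::isfinite(v[0]))
    stop("numerical error: non-finite voltage at end of simulation");
  return out;
}
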