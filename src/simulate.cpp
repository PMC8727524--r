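#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Channel kind codes shared with R/neuron_model.R (see .channel_kind_code)
enum ChannelKind { LEAK = 0, NA_HH = 1, KDR = 2, HCN = 3, KM = 4 };

// x / (1 - exp(-x / y)) with the removable singularity at x = 0 handled
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y + x / 2.0;
  return x / (1.0 - std::exp(-x / y));
}

// Fill inf/tau (size 2) for one channel at voltage v; returns gate count.
// Gate exponents are fixed per kind: Na m^3 h, Kdr n^4, HCN y, KM p.
static int gate_inf_tau(int kind, const double *p, double v,
                        double *inf, double *tau) {
  switch (kind) {
  case LEAK:
    return 0;
  case NA_HH: {
    // p: vshift_m, vshift_h (mV), rate_scale (dimensionless); activation and
    // inactivation shift independently (DRG Na currents inactivate at more
    // depolarized potentials than their activation midpoint suggests)
    const double um = v - p[0], uh = v - p[1], q = p[2];
    const double am = 0.1 * vtrap(um + 40.0, 10.0);
    const double bm = 4.0 * std::exp(-(um + 65.0) / 18.0);
    const double ah = 0.07 * std::exp(-(uh + 65.0) / 20.0);
    const double bh = 1.0 / (1.0 + std::exp(-(uh + 35.0) / 10.0));
    tau[0] = 1.0 / (q * (am + bm));
    inf[0] = am / (am + bm);
    tau[1] = 1.0 / (q * (ah + bh));
    inf[1] = ah / (ah + bh);
    return 2;
  }
  case KDR: {
    // p: vshift, rate_scale
    const double u = v - p[0], q = p[1];
    const double an = 0.01 * vtrap(u + 55.0, 10.0);
    const double bn = 0.125 * std::exp(-(u + 65.0) / 80.0);
    tau[0] = 1.0 / (q * (an + bn));
    inf[0] = an / (an + bn);
    return 1;
  }
  case HCN: {
    // p: frac, vhalf1, k1, vhalf2, k2, tau_min, tau_amp, tau_vmax,
    // tau_width. Activation increases with hyperpolarization; the steady
    // state is a two-component Boltzmann mixture (a shallow, relatively
    // depolarized HCN1-like component plus a steep hyperpolarized
    // HCN4-like component); bell-shaped time constant.
    const double b1 = 1.0 / (1.0 + std::exp((v - p[1]) / p[2]));
    const double b2 = 1.0 / (1.0 + std::exp((v - p[3]) / p[4]));
    inf[0] = p[0] * b1 + (1.0 - p[0]) * b2;
    tau[0] = p[5] + p[6] / std::cosh((v - p[7]) / p[8]);
    return 1;
  }
  case KM: {
    // p: vhalf, k, tau_ms (voltage independent)
    inf[0] = 1.0 / (1.0 + std::exp(-(v - p[0]) / p[1]));
    tau[0] = p[2];
    return 1;
  }
  default:
    stop("unknown channel kind code %d", kind);
  }
  return 0; // unreachable
}

static inline double gate_product(int kind, const double *g) {
  switch (kind) {
  case LEAK:  return 1.0;
  case NA_HH: return g[0] * g[0] * g[0] * g[1];
  case KDR:   return g[0] * g[0] * g[0] * g[0];
  case HCN:
  case KM:    return g[0];
  }
  return 1.0;
}

// Piecewise-linear stimulus lookup. segs columns: t0, t1, i0, i1 (ms, pA),
// contiguous and sorted. *seg is advanced monotonically with t.
static inline double stim_at(const NumericMatrix &segs, double t, int *seg) {
  const int n = segs.nrow();
  while (*seg < n - 1 && t >= segs(*seg, 1)) ++(*seg);
  const double t0 = segs(*seg, 0), t1 = segs(*seg, 1);
  const double i0 = segs(*seg, 2), i1 = segs(*seg, 3);
  if (t <= t0) return i0;
  if (t >= t1) return i1;
  return i0 + (i1 - i0) * (t - t0) / (t1 - t0);
}

// [[Rcpp::export]]
List cpp_gating(int kind, NumericVector params, NumericVector v) {
  const int nv = v.size();
  double inf[2], tau[2];
  const int ng = gate_inf_tau(kind, params.begin(), nv > 0 ? v[0] : -60.0,
                              inf, tau);
  NumericMatrix infm(ng, nv), taum(ng, nv);
  for (int j = 0; j < nv; ++j) {
    gate_inf_tau(kind, params.begin(), v[j], inf, tau);
    for (int g = 0; g < ng; ++g) {
      infm(g, j) = inf[g];
      taum(g, j) = tau[g];
    }
  }
  return List::create(_["inf"] = infm, _["tau"] = taum);
}

// Integrate one sweep. Gating variables use exponential Euler; the membrane
// equation, linear in V once the gates are frozen over a step, uses the exact
// exponential update toward its instantaneous equilibrium.
// [[Rcpp::export]]
List cpp_simulate(double cm, IntegerVector kinds, NumericVector gbars,
                  NumericVector erevs, List params, NumericMatrix segs,
                  double dt, int record_every, double v_init,
                  double settle_ms) {
  const int nchan = kinds.size();
  if (gbars.size() != nchan || erevs.size() != nchan ||
      params.size() != nchan)
    stop("channel argument lengths differ");
  if (cm <= 0 || dt <= 0 || record_every < 1)
    stop("invalid cm, dt or record_every");

  std::vector<std::vector<double> > par(nchan);
  std::vector<int> ngates(nchan);
  std::vector<double> gates(2 * nchan);
  double inf[2], tau[2];
  for (int c = 0; c < nchan; ++c) {
    NumericVector p = params[c];
    par[c].assign(p.begin(), p.end());
    ngates[c] = gate_inf_tau(kinds[c], par[c].data(), v_init, inf, tau);
    for (int g = 0; g < ngates[c]; ++g) gates[2 * c + g] = inf[g];
  }

  double v = v_init;

  const double T = segs(segs.nrow() - 1, 1);
  const long nsettle = (long)std::floor(settle_ms / dt + 0.5);
  const long nsteps = (long)std::floor(T / dt + 0.5);
  const long nrec = nsteps / record_every + 1;

  NumericVector tv(nrec), vv(nrec), iv(nrec);
  int seg = 0;

  for (long k = -nsettle; k <= nsteps; ++k) {
    const double t = k * dt;
    if (k >= 0 && k % record_every == 0) {
      const long r = k / record_every;
      tv[r] = t;
      vv[r] = v;
      iv[r] = stim_at(segs, t, &seg);
    }
    if (k == nsteps) break;
    const double iinj = (k < 0) ? 0.0 : stim_at(segs, t, &seg);

    double gtot = 0.0, gesum = 0.0;
    for (int c = 0; c < nchan; ++c) {
      const int ng = gate_inf_tau(kinds[c], par[c].data(), v, inf, tau);
      for (int g = 0; g < ng; ++g) {
        double &x = gates[2 * c + g];
        x = inf[g] + (x - inf[g]) * std::exp(-dt / tau[g]);
      }
      const double gc = gbars[c] * gate_product(kinds[c], &gates[2 * c]);
      gtot += gc;
      gesum += gc * erevs[c];
    }
    if (gtot <= 0) {
      v += dt * iinj / cm; // fully passive, no conductance
    } else {
      const double vinf = (gesum + iinj) / gtot;
      v = vinf + (v - vinf) * std::exp(-dt * gtot / cm);
    }
    if (!std::isfinite(v))
      stop("integration failure: non-finite voltage at t = %.3f ms", t);
  }

  // dV/dt just after settling (stimulus protocols hold 0 pA there), used to
  // verify the cell reached a fixed resting state before the stimulus
  const double end_settle_rate =
      (vv.size() >= 2) ? (vv[1] - vv[0]) / (record_every * dt) : 0.0;

  return List::create(_["t"] = tv, _["v"] = vv, _["i"] = iv,
                      _["post_settle_dvdt"] = end_settle_rate);
}
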