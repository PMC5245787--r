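// Compartmental conductance-based neuron simulator.
//
// The cell is an unbranched chain of cylindrical compartments
// (basal dendrite - soma - apical dendrite).  Voltage is advanced with a
// semi-implicit backward-Euler step (tridiagonal solve over the chain with
// channel and synaptic conductances frozen within the step); gating
// variables and the calcium pool advance by exponential Euler.  Synaptic
// conductances are dual-exponential and aggregated per compartment and
// transmitter type, so the cost per step is independent of the synapse
// count.
//
// Units: mV, ms, uS, nA, nF, uM (calcium).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct Gate { double inf, tau; };

// --- channel kinetics (HH-style, standard cortical pyramidal forms) -----

// Traub-Miles-style spike currents (robust under depolarised,
// fluctuation-driven drive); VT sets the spike threshold region.
static const double VT = -50.0;

static inline Gate na_m(double v) {
  double a = 0.32 * vtrap(v - VT - 13.0, 4.0);
  double b = 0.28 * vtrap(-(v - VT - 40.0), 5.0);
  Gate g; g.tau = 1.0 / (a + b); g.inf = a / (a + b); return g;
}
static inline Gate na_h(double v) {
  double a = 0.128 * std::exp(-(v - VT - 17.0) / 18.0);
  double b = 4.0 / (1.0 + std::exp(-(v - VT - 40.0) / 5.0));
  Gate g; g.tau = 1.0 / (a + b); g.inf = a / (a + b); return g;
}
static inline Gate kdr_n(double v) {
  double a = 0.032 * vtrap(v - VT - 15.0, 5.0);
  double b = 0.5 * std::exp(-(v - VT - 10.0) / 40.0);
  Gate g; g.tau = 1.0 / (a + b); g.inf = a / (a + b); return g;
}
static inline Gate ka_a(double v) {
  Gate g; g.inf = 1.0 / (1.0 + std::exp(-(v + 31.0) / 6.0));
  g.tau = 0.5; return g;
}
static inline Gate ka_b(double v) {
  Gate g; g.inf = 1.0 / (1.0 + std::exp((v + 66.0) / 7.0));
  g.tau = 15.0; return g;
}
static inline Gate km_u(double v) {
  double a = 0.001 * vtrap(v + 30.0, 9.0);
  double b = 0.001 * vtrap(-(v + 30.0), 9.0);
  Gate g; g.tau = 1.0 / (a + b); g.inf = a / (a + b); return g;
}
static inline Gate cah_s(double v) {
  // alpha = 0.055 (-27 - v) / (exp((-27 - v)/3.8) - 1)
  double a = 0.055 * vtrap(v + 27.0, 3.8);
  double b = 0.94 * std::exp((-75.0 - v) / 17.0);
  Gate g; g.tau = 1.0 / (a + b); g.inf = a / (a + b); return g;
}
static inline Gate kahp_q(double ca) {
  double a = std::min(0.002 * ca, 0.01);
  double b = 0.001;
  Gate g; g.tau = 1.0 / (a + b); g.inf = a / (a + b); return g;
}

static inline double gate_step(double x, const Gate &g, double dt) {
  return g.inf + (x - g.inf) * std::exp(-dt / g.tau);
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List cell, List syn, List events, List ctrl) {
  // --- cell geometry / passive -------------------------------------
  NumericVector cap = cell["cap_nF"];          // per compartment
  NumericVector gleak = cell["gleak_uS"];
  NumericVector gax = cell["gax_uS"];          // length nc-1, link i..i+1
  double eleak = as<double>(cell["e_leak"]);
  double ena = as<double>(cell["e_na"]);
  double ek = as<double>(cell["e_k"]);
  double eca = as<double>(cell["e_ca"]);
  NumericVector gna = cell["gna_uS"];
  NumericVector gkdr = cell["gkdr_uS"];
  NumericVector gka = cell["gka_uS"];
  NumericVector gkm = cell["gkm_uS"];
  NumericVector gcah = cell["gcah_uS"];
  NumericVector gkahp = cell["gkahp_uS"];
  NumericVector area = cell["area_cm2"];
  double ca_phi = as<double>(cell["ca_phi"]);  // uM cm^2 / (mA ms)
  double ca_tau = as<double>(cell["ca_tau"]);
  double ca0 = as<double>(cell["ca_rest"]);
  int nc = cap.size();

  // --- synapses ----------------------------------------------------
  IntegerVector syn_comp = syn["comp"];        // 0-based
  IntegerVector syn_type = syn["type"];        // 0 = E, 1 = I
  NumericVector syn_g = syn["g_peak_uS"];
  NumericVector tau_r = syn["tau_rise"];       // length 2 (E, I)
  NumericVector tau_d = syn["tau_decay"];
  NumericVector erev = syn["e_rev"];           // length 2

  NumericVector ev_time = events["time"];
  IntegerVector ev_syn = events["syn"];        // 0-based

  // --- control -----------------------------------------------------
  double dt = as<double>(ctrl["dt"]);
  double duration = as<double>(ctrl["duration"]);
  int rec_every = as<int>(ctrl["rec_every"]);
  double v_init = as<double>(ctrl["v_init"]);
  int clamp_mode = as<int>(ctrl["clamp_mode"]); // 0 free, 1 space, 2 soma
  double v_hold = as<double>(ctrl["v_hold"]);
  bool na_off = as<bool>(ctrl["na_off"]);
  bool passive_only = as<bool>(ctrl["passive_only"]);
  IntegerVector soma_idx = ctrl["soma_idx"];   // 0-based
  double i_inj = as<double>(ctrl["i_inj"]);
  double inj_start = as<double>(ctrl["inj_start"]);
  double inj_end = as<double>(ctrl["inj_end"]);
  double spike_thresh = as<double>(ctrl["spike_thresh"]);
  double refractory = as<double>(ctrl["refractory"]);

  int nstep = (int)std::round(duration / dt);
  int nrec = nstep / rec_every + 1;

  // state
  std::vector<double> v(nc, clamp_mode ? v_hold : v_init);
  std::vector<double> m(nc), h(nc), n(nc), aa(nc), bb(nc), u(nc), s(nc),
      q(nc), ca(nc, ca0);
  for (int i = 0; i < nc; ++i) {
    m[i] = na_m(v[i]).inf; h[i] = na_h(v[i]).inf; n[i] = kdr_n(v[i]).inf;
    aa[i] = ka_a(v[i]).inf; bb[i] = ka_b(v[i]).inf; u[i] = km_u(v[i]).inf;
    s[i] = cah_s(v[i]).inf; q[i] = kahp_q(ca[i]).inf;
  }
  // aggregated dual-exponential synaptic states per compartment x type
  std::vector<double> sA(2 * nc, 0.0), sB(2 * nc, 0.0);
  double fr[2], fd[2], norm[2];
  for (int ty = 0; ty < 2; ++ty) {
    fr[ty] = std::exp(-dt / tau_r[ty]);
    fd[ty] = std::exp(-dt / tau_d[ty]);
    double tp = std::log(tau_d[ty] / tau_r[ty]) * tau_r[ty] * tau_d[ty] /
                (tau_d[ty] - tau_r[ty]);
    norm[ty] = std::exp(-tp / tau_d[ty]) - std::exp(-tp / tau_r[ty]);
  }

  // tridiagonal workspace
  std::vector<double> lo(nc), di(nc), up(nc), rhs(nc), cp(nc), dp(nc);

  NumericVector out_t(nrec), out_v(nrec), out_ie(nrec), out_ii(nrec),
      out_ca(nrec), out_iclamp(nrec);
  std::vector<double> spikes;
  double last_spike = -1e9;
  bool above = false;
  int iev = 0, nev = ev_time.size(), irec = 0;
  int soma0 = soma_idx[0];
  int ca_comp = -1;
  for (int i = 0; i < nc; ++i) if (gcah[i] > 0) { ca_comp = i; break; }

  for (int step = 0; step <= nstep; ++step) {
    double t = step * dt;

    // record
    if (step % rec_every == 0 && irec < nrec) {
      double ie = 0.0, ii = 0.0;
      for (int i = 0; i < nc; ++i) {
        double gE = (sB[i] - sA[i]) / norm[0];
        double gI = (sB[nc + i] - sA[nc + i]) / norm[1];
        ie += gE * (v[i] - erev[0]);
        ii += gI * (v[i] - erev[1]);
      }
      out_t[irec] = t;
      out_v[irec] = v[soma0];
      out_ie[irec] = ie;   // nA; negative = inward (depolarising)
      out_ii[irec] = ii;
      out_ca[irec] = ca_comp >= 0 ? ca[ca_comp] : ca0;
      if (clamp_mode == 2) {
        // electrode current holding the soma: membrane + axial at clamped comps
        double icl = 0.0;
        for (int k = 0; k < soma_idx.size(); ++k) {
          int i = soma_idx[k];
          double gE = (sB[i] - sA[i]) / norm[0];
          double gI = (sB[nc + i] - sA[nc + i]) / norm[1];
          icl += gleak[i] * (v[i] - eleak) + gE * (v[i] - erev[0]) +
                 gI * (v[i] - erev[1]);
          if (i > 0) icl += gax[i - 1] * (v[i] - v[i - 1]);
          if (i < nc - 1) icl += gax[i] * (v[i] - v[i + 1]);
        }
        out_iclamp[irec] = icl;
      }
      irec++;
    }
    if (step == nstep) break;

    // deliver events with time in [t, t+dt)
    while (iev < nev && ev_time[iev] < t + dt) {
      int sidx = ev_syn[iev];
      int ty = syn_type[sidx];
      int cix = ty * nc + syn_comp[sidx];
      sA[cix] += syn_g[sidx];
      sB[cix] += syn_g[sidx];
      ++iev;
    }
    // decay synaptic states
    for (int i = 0; i < nc; ++i) {
      sA[i] *= fr[0]; sB[i] *= fd[0];
      sA[nc + i] *= fr[1]; sB[nc + i] *= fd[1];
    }

    // gating + calcium (exponential Euler at current V)
    if (!passive_only) {
      for (int i = 0; i < nc; ++i) {
        if (gna[i] > 0) {
          m[i] = gate_step(m[i], na_m(v[i]), dt);
          h[i] = gate_step(h[i], na_h(v[i]), dt);
        }
        if (gkdr[i] > 0) n[i] = gate_step(n[i], kdr_n(v[i]), dt);
        if (gka[i] > 0) {
          aa[i] = gate_step(aa[i], ka_a(v[i]), dt);
          bb[i] = gate_step(bb[i], ka_b(v[i]), dt);
        }
        if (gkm[i] > 0) u[i] = gate_step(u[i], km_u(v[i]), dt);
        if (gcah[i] > 0) {
          s[i] = gate_step(s[i], cah_s(v[i]), dt);
          double ica = gcah[i] * s[i] * s[i] * (v[i] - eca); // nA
          double influx = -ca_phi * (ica * 1e-6 / area[i]);  // uM/ms
          if (influx < 0) influx = 0;
          // linear ODE: ca' = influx - (ca - ca0)/tau
          double target = ca0 + influx * ca_tau;
          ca[i] = target + (ca[i] - target) * std::exp(-dt / ca_tau);
        }
        if (gkahp[i] > 0) q[i] = gate_step(q[i], kahp_q(ca[i]), dt);
      }
    }

    if (clamp_mode == 1) continue;  // space clamp: voltages fixed

    // assemble tridiagonal system
    for (int i = 0; i < nc; ++i) {
      double gE = (sB[i] - sA[i]) / norm[0];
      double gI = (sB[nc + i] - sA[nc + i]) / norm[1];
      double gtot = gleak[i] + gE + gI;
      double src = gleak[i] * eleak + gE * erev[0] + gI * erev[1];
      if (!passive_only) {
        double gNa = na_off ? 0.0 : gna[i] * m[i] * m[i] * m[i] * h[i];
        double gK = gkdr[i] * n[i] * n[i] * n[i] * n[i] +
                    gka[i] * aa[i] * aa[i] * aa[i] * aa[i] * bb[i] +
                    gkm[i] * u[i] + gkahp[i] * q[i];
        double gCa = gcah[i] * s[i] * s[i];
        gtot += gNa + gK + gCa;
        src += gNa * ena + gK * ek + gCa * eca;
      }
      double cdt = cap[i] / dt;
      di[i] = cdt + gtot;
      rhs[i] = cdt * v[i] + src;
      lo[i] = 0.0; up[i] = 0.0;
      if (i > 0) { lo[i] = -gax[i - 1]; di[i] += gax[i - 1]; }
      if (i < nc - 1) { up[i] = -gax[i]; di[i] += gax[i]; }
    }
    if (i_inj != 0.0 && t >= inj_start && t < inj_end) {
      rhs[soma0] += i_inj;
    }
    if (clamp_mode == 2) {
      for (int k = 0; k < soma_idx.size(); ++k) {
        int i = soma_idx[k];
        lo[i] = 0.0; up[i] = 0.0; di[i] = 1.0; rhs[i] = v_hold;
        // neighbours still see the clamped potential through lo/up terms
      }
    }
    // Thomas algorithm
    cp[0] = up[0] / di[0];
    dp[0] = rhs[0] / di[0];
    for (int i = 1; i < nc; ++i) {
      double mlt = di[i] - lo[i] * cp[i - 1];
      cp[i] = up[i] / mlt;
      dp[i] = (rhs[i] - lo[i] * dp[i - 1]) / mlt;
    }
    v[nc - 1] = dp[nc - 1];
    for (int i = nc - 2; i >= 0; --i) v[i] = dp[i] - cp[i] * v[i + 1];

    // spike detection on somatic voltage
    double vs = v[soma0];
    if (!above && vs >= spike_thresh) {
      double ts = t + dt;
      if (ts - last_spike >= refractory) {
        spikes.push_back(ts);
        last_spike = ts;
      }
      above = true;
    } else if (above && vs < spike_thresh) {
      above = false;
    }
  }

  return List::create(
      _["time"] = out_t, _["v_soma"] = out_v, _["i_excit"] = out_ie,
      _["i_inhib"] = out_ii, _["ca"] = out_ca, _["i_clamp"] = out_iclamp,
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()));
}
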