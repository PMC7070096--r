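// Clock-driven integrator for the multicolumn aEIF network.
//
// Per step, in fixed order: (1) deliver delayed synaptic events and
// external stimulus spikes into the per-neuron receptor conductance
// states, (2) compute synaptic + background currents, (3) explicit-Euler
// update of all neuron states, (4) detect V_peak crossings, apply the
// reset rule and enqueue emitted spikes at t + tau_D with the
// short-term-plasticity efficacy frozen at emission.
//
// Each double-exponential kernel is carried as two first-order decay
// states per receptor per neuron (x_off, x_on both incremented by the
// synaptic weight on arrival), which reproduces the explicit spike-sum
// form of the conductance exactly.
//
// Synapses sharing a presynaptic neuron and an STP parameter triple see
// the same spike train, so their Tsodyks-Markram states are identical;
// the engine keeps one state per (neuron, triple) and stamps the
// efficacy into the queued delivery, which is equivalent to per-synapse
// state at a fraction of the cost.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

#define MAX_STP_CLASSES 8

struct Delivery {
  int rangeStart, rangeEnd;           // synapse slice (reordered arrays)
  double eff[MAX_STP_CLASSES];        // per-class efficacy at emission
};

// [[Rcpp::export]]
List run_network_cpp(List neurons, List synapses, List receptors,
                     IntegerVector stim_neuron, NumericVector stim_time,
                     double stim_weight, double dt, int n_steps,
                     bool stp_r1_complement) {
  NumericVector C = neurons["C_m_pF"], gL = neurons["g_L_nS"],
                EL = neurons["E_L_mV"], Vth = neurons["V_th_mV"],
                DT = neurons["Delta_T_mV"], tauw = neurons["tau_w_ms"],
                a = neurons["a_nS"], b = neurons["b_pA"],
                Vr = neurons["V_r_mV"], Vpk = neurons["V_peak_mV"],
                Ibg = neurons["I_bg_pA"], wMin = neurons["w_min_pA"];
  const int N = C.size();

  IntegerVector s_pre = synapses["pre0"], s_post = synapses["post0"],
                s_dsteps = synapses["delay_steps"];
  NumericVector s_gA = synapses["g_ampa_nS"], s_gN = synapses["g_nmda_nS"],
                s_gG = synapses["g_gabaa_nS"], s_U = synapses["U"],
                s_tf = synapses["tau_facil_ms"], s_tr = synapses["tau_rec_ms"];
  const int M = s_pre.size();

  NumericVector r_ton = receptors["tau_on_ms"], r_toff = receptors["tau_off_ms"],
                r_erev = receptors["E_rev_mV"];   // order: AMPA, NMDA, GABAA

  // STP parameter classes (unique triples)
  std::vector<double> cU, cTf, cTr;
  std::vector<int> s_cls(M);
  for (int k = 0; k < M; ++k) {
    int c = -1;
    for (size_t j = 0; j < cU.size(); ++j)
      if (cU[j] == s_U[k] && cTf[j] == s_tf[k] && cTr[j] == s_tr[k]) {
        c = (int)j; break;
      }
    if (c < 0) {
      if (cU.size() >= MAX_STP_CLASSES)
        stop("too many distinct STP parameter triples (max %d)",
             MAX_STP_CLASSES);
      cU.push_back(s_U[k]); cTf.push_back(s_tf[k]); cTr.push_back(s_tr[k]);
      c = (int)cU.size() - 1;
    }
    s_cls[k] = c;
  }
  const int NC = (int)cU.size();

  // order synapses by (pre, delay) so each (neuron, delay) is one slice
  std::vector<int> order(M);
  for (int k = 0; k < M; ++k) order[k] = k;
  std::stable_sort(order.begin(), order.end(), [&](int x, int y) {
    if (s_pre[x] != s_pre[y]) return s_pre[x] < s_pre[y];
    return s_dsteps[x] < s_dsteps[y];
  });
  std::vector<int> o_post(M), o_cls(M);
  std::vector<double> o_gA(M), o_gN(M), o_gG(M);
  for (int q = 0; q < M; ++q) {
    int k = order[q];
    o_post[q] = s_post[k]; o_cls[q] = s_cls[k];
    o_gA[q] = s_gA[k]; o_gN[q] = s_gN[k]; o_gG[q] = s_gG[k];
  }
  // per-neuron (delay, slice) groups
  std::vector<int> grp_first(N + 1, 0);
  std::vector<int> grp_delay, grp_start, grp_end;
  {
    int q = 0;
    for (int i = 0; i < N; ++i) {
      grp_first[i] = (int)grp_delay.size();
      while (q < M && s_pre[order[q]] == i) {
        int d = s_dsteps[order[q]];
        int start = q;
        while (q < M && s_pre[order[q]] == i && s_dsteps[order[q]] == d) ++q;
        grp_delay.push_back(d);
        grp_start.push_back(start);
        grp_end.push_back(q);
      }
    }
    grp_first[N] = (int)grp_delay.size();
  }

  // one STP state per (neuron, class); lazily bound to classes actually
  // present on that neuron (advanced once per spike, all classes alike)
  std::vector<double> u(N * NC), R(N * NC), tlast(N * NC);
  std::vector<char> fired(N * NC, 0);
  for (int i = 0; i < N * NC; ++i) {
    int c = i % NC;
    u[i] = cU[c];
    R[i] = stp_r1_complement ? 1.0 - cU[c] : 1.0;
    tlast[i] = 0.0;
  }

  // conductance decay states: [receptor][neuron]
  std::vector<std::vector<double> > xon(3, std::vector<double>(N, 0.0)),
                                    xoff(3, std::vector<double>(N, 0.0));
  double dOn[3], dOff[3];
  for (int r = 0; r < 3; ++r) {
    dOn[r] = std::exp(-dt / r_ton[r]);
    dOff[r] = std::exp(-dt / r_toff[r]);
  }

  int maxDelay = 0;
  for (int k = 0; k < M; ++k) if (s_dsteps[k] > maxDelay) maxDelay = s_dsteps[k];
  const int L = maxDelay + 2;
  std::vector<std::vector<Delivery> > ring(L);

  // external stimulus events grouped by step
  const int nStim = stim_neuron.size();
  std::vector<int> stimStep(nStim), stimOrd(nStim);
  for (int k = 0; k < nStim; ++k) {
    stimStep[k] = (int)std::lround(stim_time[k] / dt);
    stimOrd[k] = k;
  }
  std::stable_sort(stimOrd.begin(), stimOrd.end(),
                   [&](int x, int y) { return stimStep[x] < stimStep[y]; });
  int stimPtr = 0;

  std::vector<double> V(N), w(N);
  for (int i = 0; i < N; ++i) { V[i] = EL[i]; w[i] = 0.0; }

  std::vector<int> out_id; std::vector<double> out_t;
  out_id.reserve(1 << 16); out_t.reserve(1 << 16);

  double effs[MAX_STP_CLASSES];

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    // (1) deliveries
    std::vector<Delivery> &slot = ring[s % L];
    for (size_t e = 0; e < slot.size(); ++e) {
      const Delivery &dv = slot[e];
      for (int q = dv.rangeStart; q < dv.rangeEnd; ++q) {
        const double eff = dv.eff[o_cls[q]];
        const int p = o_post[q];
        if (o_gA[q] != 0) {
          const double wA = eff * o_gA[q];
          xon[0][p] += wA; xoff[0][p] += wA;
        }
        if (o_gN[q] != 0) {
          const double wN = eff * o_gN[q];
          xon[1][p] += wN; xoff[1][p] += wN;
        }
        if (o_gG[q] != 0) {
          const double wG = eff * o_gG[q];
          xon[2][p] += wG; xoff[2][p] += wG;
        }
      }
    }
    slot.clear();
    while (stimPtr < nStim && stimStep[stimOrd[stimPtr]] == s) {
      int tgt = stim_neuron[stimOrd[stimPtr]];
      xon[0][tgt] += stim_weight; xoff[0][tgt] += stim_weight;
      ++stimPtr;
    }

    // (2)+(3) currents and Euler update; (4) reset; decay fused in
    for (int i = 0; i < N; ++i) {
      const double Vi = V[i];
      double gA = xoff[0][i] - xon[0][i];
      double gN = xoff[1][i] - xon[1][i];
      double gG = xoff[2][i] - xon[2][i];
      double Isyn = gA * (r_erev[0] - Vi) + gG * (r_erev[2] - Vi);
      if (gN != 0) {
        const double sN = 1.08 / (1.0 + 0.19 * std::exp(-0.064 * Vi));
        Isyn += sN * gN * (r_erev[1] - Vi);
      }
      double vexp = Vi < Vpk[i] ? Vi : Vpk[i];
      double dV = (-gL[i] * (Vi - EL[i]) +
                   gL[i] * DT[i] * std::exp((vexp - Vth[i]) / DT[i]) +
                   Ibg[i] + Isyn - w[i]) / C[i];
      double dw = (a[i] * (Vi - EL[i]) - w[i]) / tauw[i];
      double Vn = Vi + dt * dV;
      double wn = w[i] + dt * dw;
      if (!std::isfinite(Vn) || !std::isfinite(wn))
        stop("non-finite state in neuron %d at t = %.2f ms", i + 1, t);
      if (wn < wMin[i]) wn = wMin[i];
      if (Vn >= Vpk[i]) {
        const double ts = t + dt;
        V[i] = Vr[i]; w[i] = wn + b[i];
        if (w[i] < wMin[i]) w[i] = wMin[i];
        out_id.push_back(i + 1); out_t.push_back(ts);
        if (grp_first[i] < grp_first[i + 1]) {
          // advance every STP class present for this neuron once
          for (int c = 0; c < NC; ++c) {
            const int idx = i * NC + c;
            if (!fired[idx]) {
              fired[idx] = 1;
              effs[c] = u[idx] * R[idx];
            } else {
              const double dtk = ts - tlast[idx];
              const double ef = std::exp(-dtk / cTf[c]);
              const double er = std::exp(-dtk / cTr[c]);
              const double un = u[idx] * ef + cU[c] * (1.0 - u[idx] * ef);
              R[idx] = R[idx] * (1.0 - un) * er + 1.0 - er;
              u[idx] = un;
              effs[c] = un * R[idx];
            }
            tlast[idx] = ts;
          }
          for (int g = grp_first[i]; g < grp_first[i + 1]; ++g) {
            Delivery dv;
            dv.rangeStart = grp_start[g]; dv.rangeEnd = grp_end[g];
            for (int c = 0; c < NC; ++c) dv.eff[c] = effs[c];
            ring[(s + 1 + grp_delay[g]) % L].push_back(dv);
          }
        }
      } else {
        V[i] = Vn; w[i] = wn;
      }
      xon[0][i] *= dOn[0]; xoff[0][i] *= dOff[0];
      xon[1][i] *= dOn[1]; xoff[1][i] *= dOff[1];
      xon[2][i] *= dOn[2]; xoff[2][i] *= dOff[2];
    }
  }

  return List::create(_["id"] = wrap(out_id), _["time_ms"] = wrap(out_t),
                      _["V"] = wrap(std::vector<double>(V.begin(), V.end())),
                      _["w"] = wrap(std::vector<double>(w.begin(), w.end())));
}
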