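#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire simulation of one antennal-lobe glomerulus
// (PNs with SK adaptation + LNs). Time unit: ms. Conductances decay
// exponentially between events (exact update); membrane potentials use
// explicit Euler; the two-state SK cascade uses Euler for the rise stage.
// Each presynaptic spike kicks the target conductance by its amplitude
// S_X (kick-and-decay convention of the glomerulus-model literature) and
// each PN spike kicks its own SK drive z by S_SK.
// ORN input (background + stimulus) arrives as independent Poisson event
// counts per neuron per step, drawn from R's RNG (seed determinism is
// handled by the caller via set.seed()).
// [[Rcpp::export]]
List al_sim_cpp(IntegerMatrix A_pp, IntegerMatrix A_pl, IntegerMatrix A_lp,
                IntegerMatrix A_ll, NumericVector s_sk,
                NumericVector orn_rate, double dt, int n_steps,
                List pars, bool record = false, int record_idx = 0) {
  int n_pn = A_pp.nrow();
  int n_ln = A_ll.nrow();
  int n = n_pn + n_ln;

  double tau_v   = pars["tau_v"],   tau_ref  = pars["tau_ref"];
  double tau_exc = pars["tau_exc"], tau_inh  = pars["tau_inh"];
  double tau_slow = pars["tau_slow"], tau_stim = pars["tau_stim"];
  double tau_rise = pars["tau_rise"], tau_sk = pars["tau_sk"];
  double e_l = pars["e_l"], e_exc = pars["e_exc"], e_inh = pars["e_inh"];
  double e_stim = pars["e_stim"], e_sk = pars["e_sk"], v_thr = pars["v_thr"];
  NumericVector S_exc = pars["S_exc"];   // (PN, LN) postsynaptic amplitudes
  NumericVector S_inh = pars["S_inh"];
  NumericVector S_slow = pars["S_slow"];
  NumericVector S_stim = pars["S_stim"];

  double d_exc = std::exp(-dt / tau_exc), d_inh = std::exp(-dt / tau_inh);
  double d_slow = std::exp(-dt / tau_slow), d_stim = std::exp(-dt / tau_stim);
  double d_sk = std::exp(-dt / tau_sk);

  std::vector<double> V(n, e_l), g_exc(n, 0.0), g_inh(n, 0.0),
      g_slow(n, 0.0), g_stim(n, 0.0), g_sk(n_pn, 0.0), z(n_pn, 0.0),
      ref_until(n, -1.0);
  std::vector<std::vector<double> > spikes(n);

  int rec_n = record ? n_steps : 0;
  NumericMatrix rec(rec_n, record ? 7 : 0);

  RNGScope scope;
  for (int s = 0; s < n_steps; s++) {
    double t = s * dt;
    double lam = orn_rate[s] * dt;  // expected ORN events per neuron, this step

    // conductance decay (exact) and SK rise stage (Euler)
    for (int i = 0; i < n; i++) {
      g_exc[i] *= d_exc; g_inh[i] *= d_inh;
      g_slow[i] *= d_slow; g_stim[i] *= d_stim;
    }
    for (int i = 0; i < n_pn; i++) {
      z[i] *= d_sk;
      g_sk[i] += dt * (z[i] - g_sk[i]) / tau_rise;
    }

    // ORN Poisson drive, independent across neurons
    if (lam > 0) {
      for (int i = 0; i < n; i++) {
        double k = R::rpois(lam);
        if (k > 0)
          g_stim[i] += k * S_stim[i < n_pn ? 0 : 1];
      }
    }

    if (record) {
      int i = record_idx;
      rec(s, 0) = V[i]; rec(s, 1) = g_stim[i]; rec(s, 2) = g_exc[i];
      rec(s, 3) = g_inh[i]; rec(s, 4) = g_slow[i];
      rec(s, 5) = (i < n_pn) ? g_sk[i] : 0.0;
      rec(s, 6) = (i < n_pn) ? z[i] : 0.0;
    }

    // membrane update
    for (int i = 0; i < n; i++) {
      if (t < ref_until[i]) { V[i] = e_l; continue; }
      double dv = -(V[i] - e_l) / tau_v
        - g_stim[i] * (V[i] - e_stim)
        - g_exc[i] * (V[i] - e_exc)
        - g_inh[i] * (V[i] - e_inh)
        - g_slow[i] * (V[i] - e_inh);
      if (i < n_pn) dv -= g_sk[i] * (V[i] - e_sk);
      V[i] += dt * dv;
    }

    // threshold crossing, reset, synaptic delivery
    for (int i = 0; i < n; i++) {
      if (t < ref_until[i] || V[i] < v_thr) continue;
      spikes[i].push_back(t);
      V[i] = e_l;
      ref_until[i] = t + tau_ref;
      if (i < n_pn) {             // PN spike: excitatory + own SK
        z[i] += s_sk[i];
        for (int j = 0; j < n_pn; j++)
          if (A_pp(i, j)) g_exc[j] += S_exc[0];
        for (int j = 0; j < n_ln; j++)
          if (A_pl(i, j)) g_exc[n_pn + j] += S_exc[1];
      } else {                    // LN spike: fast + slow inhibition
        int li = i - n_pn;
        for (int j = 0; j < n_pn; j++)
          if (A_lp(li, j)) {
            g_inh[j] += S_inh[0];
            g_slow[j] += S_slow[0];
          }
        for (int j = 0; j < n_ln; j++)
          if (A_ll(li, j)) {
            g_inh[n_pn + j] += S_inh[1];
            g_slow[n_pn + j] += S_slow[1];
          }
      }
    }
  }

  List out_spikes(n);
  for (int i = 0; i < n; i++) out_spikes[i] = wrap(spikes[i]);
  List out = List::create(_["spikes"] = out_spikes);
  if (record) out["trace"] = rec;
  return out;
}
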