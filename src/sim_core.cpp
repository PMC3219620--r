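// Clock-driven integration of the striatal LIF network.
//
// State per neuron: membrane potential V plus two linear kernel states per
// synapse class (excitatory, inhibitory) realizing the alpha-function
// conductance transient g(t) = peak * (t/tau) * exp(1 - t/tau) exactly on the
// time grid.  A presynaptic spike adds an impulse A = peak * e / tau to the
// first kernel state y1; then
//     y1' = -y1/tau,   y2' = -y2/tau + y1,   g(t) = y2(t)
// which is advanced exactly over a step dt by
//     y2 <- E*(y2 + dt*y1),  y1 <- E*y1,  E = exp(-dt/tau).
// The membrane update uses the exact average of g over the step,
//     gbar = [ y2*tau*(1-E) + y1*(tau^2*(1-E) - tau*dt*E) ] / dt,
// held constant in an exponential-Euler update of the conductance-based
// membrane equation  C dV/dt = -gL(V-EL) - Ge(V-Ee) - Gi(V-Ei) + I.
//
// Units: mV, ms, nS, pF; currents come out in pA (nS*mV) and C/gL in ms.
//
// Randomness (background Poisson input, one count per neuron per step) uses
// R's RNG so that set.seed() in R makes runs bit-identical.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List sim_core(int n_msn, int n_fsi,
              NumericVector Cm, NumericVector gL, NumericVector EL,
              NumericVector Eexc, NumericVector Einh, NumericVector Vth,
              NumericVector tau_e, NumericVector tau_i, NumericVector t_ref,
              NumericVector bg_rate, NumericVector bg_peak,
              List mm_targets, List fm_targets,
              double g_fb, double g_ff, double d_fb, double d_ff,
              List stim_times, List stim_mult,
              IntegerVector forced_ids, List forced_times,
              NumericVector I_inj, NumericVector V0,
              IntegerVector clone_ids, double rec_start, double rec_end,
              double dt, double duration) {
  const int N = n_msn + n_fsi;
  const int n_steps = (int) std::floor(duration / dt + 0.5);
  const double e1 = std::exp(1.0);

  // per-neuron precomputed constants
  std::vector<double> Ee(N), Ei(N), a1e(N), a2e(N), a1i(N), a2i(N),
      amp_e(N), lam_bg(N);
  std::vector<int> ref_steps(N);
  for (int n = 0; n < N; ++n) {
    double te = tau_e[n], ti = tau_i[n];
    Ee[n] = std::exp(-dt / te);
    Ei[n] = std::exp(-dt / ti);
    a2e[n] = te * (1.0 - Ee[n]) / dt;
    a1e[n] = (te * te * (1.0 - Ee[n]) - te * dt * Ee[n]) / dt;
    a2i[n] = ti * (1.0 - Ei[n]) / dt;
    a1i[n] = (ti * ti * (1.0 - Ei[n]) - ti * dt * Ei[n]) / dt;
    amp_e[n] = bg_peak[n] * e1 / te;        // impulse per background/stimulus spike
    lam_bg[n] = bg_rate[n] * dt * 1e-3;     // Hz * ms -> expected count per step
    ref_steps[n] = (int) std::floor(t_ref[n] / dt + 0.5);
  }

  const int dfb = (int) std::floor(d_fb / dt + 0.5);
  const int dff = (int) std::floor(d_ff / dt + 0.5);
  const int L = std::max(dfb, dff) + 1;     // ring buffer length

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> y1e(N, 0.0), y2e(N, 0.0), y1i(N, 0.0), y2i(N, 0.0);
  std::vector<int> ref_until(N, -1);
  std::vector< std::vector<double> > inh_buf(L, std::vector<double>(N, 0.0));

  // forced spike sources (their V is never integrated, they only emit)
  std::vector<bool> is_forced(N, false);
  std::vector<int> forced_ptr(forced_ids.size(), 0);
  std::vector<NumericVector> ftrains;
  for (int k = 0; k < forced_ids.size(); ++k) {
    is_forced[forced_ids[k]] = true;
    ftrains.push_back(as<NumericVector>(forced_times[k]));
  }

  // stimulus pointers (aggregate trains: times + multiplicities per neuron)
  std::vector<int> stim_ptr(N, 0);
  std::vector<NumericVector> stimes(N), smult(N);
  bool any_stim = stim_times.size() > 0;
  if (any_stim) {
    for (int n = 0; n < N; ++n) {
      stimes[n] = as<NumericVector>(stim_times[n]);
      smult[n] = as<NumericVector>(stim_mult[n]);
    }
  }

  // clones: non-spiking twins with their own kernel states (a clone keeps
  // integrating every input, including input its twin discards while
  // refractory, and never resets)
  const int n_clones = clone_ids.size();
  std::vector<int> clone_slot(N, -1);
  std::vector<double> Vc(n_clones), c1e(n_clones, 0.0), c2e(n_clones, 0.0),
      c1i(n_clones, 0.0), c2i(n_clones, 0.0);
  for (int k = 0; k < n_clones; ++k) {
    clone_slot[clone_ids[k]] = k;
    Vc[k] = V0[clone_ids[k]];
  }
  int rec_first = (int) std::ceil(rec_start / dt - 1e-9);
  int rec_last = std::min(n_steps, (int) std::floor(rec_end / dt + 1e-9));
  if (rec_first < 0) rec_first = 0;
  int n_rec = (n_clones > 0 && rec_last > rec_first) ? rec_last - rec_first : 0;
  NumericMatrix vm(n_rec, n_clones);
  NumericVector vm_time(n_rec);

  std::vector<int> out_id;
  std::vector<double> out_t;
  out_id.reserve(1 << 16);
  out_t.reserve(1 << 16);

  RNGScope rng;

  std::vector<int> spiking;  // spike emitters this step
  for (int ts = 0; ts < n_steps; ++ts) {
    const double t1 = (ts + 1) * dt;
    if (ts % 2000 == 0) checkUserInterrupt();

    // 1. deliver delayed inhibitory impulses scheduled for this step
    std::vector<double>& slot = inh_buf[ts % L];
    for (int n = 0; n < N; ++n) {
      double b = slot[n];
      if (b != 0.0) {
        if (ts >= ref_until[n]) y1i[n] += b;   // discarded while refractory
        int cs = clone_slot[n];
        if (cs >= 0) c1i[cs] += b;
        slot[n] = 0.0;
      }
    }

    // 2. excitatory impulses: background Poisson + stimulus aggregate
    for (int n = 0; n < N; ++n) {
      if (is_forced[n]) continue;
      double add = 0.0;
      if (lam_bg[n] > 0.0) {
        double k = R::rpois(lam_bg[n]);
        if (k > 0.0) add += k * amp_e[n];
      }
      if (any_stim) {
        const NumericVector& tt = stimes[n];
        const NumericVector& mm = smult[n];
        int& p = stim_ptr[n];
        while (p < tt.size() && tt[p] < t1) {
          add += mm[p] * amp_e[n];
          ++p;
        }
      }
      if (add != 0.0) {
        if (ts >= ref_until[n]) y1e[n] += add;
        int cs = clone_slot[n];
        if (cs >= 0) c1e[cs] += add;
      }
    }

    // 3. integrate membranes, detect threshold crossings
    spiking.clear();
    for (int n = 0; n < N; ++n) {
      if (is_forced[n]) continue;
      double ge = a1e[n] * y1e[n] + a2e[n] * y2e[n];
      double gi = a1i[n] * y1i[n] + a2i[n] * y2i[n];
      y2e[n] = Ee[n] * (y2e[n] + dt * y1e[n]);
      y1e[n] *= Ee[n];
      y2i[n] = Ei[n] * (y2i[n] + dt * y1i[n]);
      y1i[n] *= Ei[n];
      if (ts < ref_until[n]) {
        V[n] = EL[n];
        continue;
      }
      double gt = gL[n] + ge + gi;
      double vinf = (gL[n] * EL[n] + ge * Eexc[n] + gi * Einh[n] + I_inj[n]) / gt;
      V[n] = vinf + (V[n] - vinf) * std::exp(-gt * dt / Cm[n]);
      if (V[n] >= Vth[n]) {
        out_id.push_back(n + 1);
        out_t.push_back(t1);
        V[n] = EL[n];
        ref_until[n] = ts + 1 + ref_steps[n];
        spiking.push_back(n);
      }
    }

    // clones: same inputs, no threshold/reset
    for (int k = 0; k < n_clones; ++k) {
      int n = clone_ids[k];
      double ge = a1e[n] * c1e[k] + a2e[n] * c2e[k];
      double gi = a1i[n] * c1i[k] + a2i[n] * c2i[k];
      c2e[k] = Ee[n] * (c2e[k] + dt * c1e[k]);
      c1e[k] *= Ee[n];
      c2i[k] = Ei[n] * (c2i[k] + dt * c1i[k]);
      c1i[k] *= Ei[n];
      double gt = gL[n] + ge + gi;
      double vinf = (gL[n] * EL[n] + ge * Eexc[n] + gi * Einh[n] + I_inj[n]) / gt;
      Vc[k] = vinf + (Vc[k] - vinf) * std::exp(-gt * dt / Cm[n]);
    }
    if (n_rec > 0 && ts >= rec_first && ts < rec_last) {
      int row = ts - rec_first;
      vm_time[row] = t1;
      for (int k = 0; k < n_clones; ++k) vm(row, k) = Vc[k];
    }

    // forced FSI sources emit prescribed spikes this step
    for (int k = 0; k < (int) ftrains.size(); ++k) {
      const NumericVector& tt = ftrains[k];
      int& p = forced_ptr[k];
      while (p < tt.size() && tt[p] < t1) {
        out_id.push_back(forced_ids[k] + 1);
        out_t.push_back(t1);
        spiking.push_back(forced_ids[k]);
        ++p;
      }
    }

    // 4. enqueue delayed inhibition from this step's spikes
    for (size_t s = 0; s < spiking.size(); ++s) {
      int n = spiking[s];
      if (n < n_msn) {                                  // MSN -> MSN feedback
        int arr = ts + dfb;
        if (arr >= n_steps) continue;
        std::vector<double>& dst = inh_buf[arr % L];
        IntegerVector tg = mm_targets[n];
        for (int j = 0; j < tg.size(); ++j) {
          int m = tg[j];
          dst[m] += g_fb * e1 / tau_i[m];
        }
      } else {                                          // FSI -> MSN feedforward
        int arr = ts + dff;
        if (arr >= n_steps) continue;
        std::vector<double>& dst = inh_buf[arr % L];
        IntegerVector tg = fm_targets[n - n_msn];
        for (int j = 0; j < tg.size(); ++j) {
          int m = tg[j];
          dst[m] += g_ff * e1 / tau_i[m];
        }
      }
    }

    if (ts % 5000 == 4999) {
      for (int n = 0; n < N; ++n)
        if (!R_finite(V[n]) && !is_forced[n])
          stop("non-finite membrane potential at t = %f ms (neuron %d)", t1, n + 1);
    }
  }

  for (int n = 0; n < N; ++n)
    if (!R_finite(V[n]) && !is_forced[n])
      stop("non-finite membrane potential at end of run (neuron %d)", n + 1);

  return List::create(_["id"] = wrap(out_id), _["time"] = wrap(out_t),
                      _["vm"] = vm, _["vm_time"] = vm_time);
}
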