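// Clocked leaky integrate-and-fire network core.
//
// Forward-Euler membrane integration at fixed dt with exact exponential
// conductance decay between spikes; spike delivery through a ring buffer
// realizing the synaptic latency (rounded to an integer number of steps);
// optional inhibitory STDP on I->E weights; optional Poisson delta-current
// external drive. All randomness comes from R's RNG so that set.seed() in R
// makes runs byte-for-byte reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List lif_simulate(List cfg, List net, List proto) {
  // --- scalar configuration -------------------------------------------------
  const double dt      = as<double>(cfg["dt"]);       // ms
  const int    nsteps  = as<int>(cfg["n_steps"]);
  const double Cm      = as<double>(cfg["C"]);        // pF
  const double gleak   = as<double>(cfg["g_leak"]);   // nS
  const double Vrest   = as<double>(cfg["V_rest"]);   // mV
  const double Vthr    = as<double>(cfg["V_thr"]);    // mV
  const double taurefr = as<double>(cfg["tau_refr"]); // ms
  const double taul    = as<double>(cfg["tau_l"]);    // ms
  const double Ibg     = as<double>(cfg["I_bg"]);     // pA
  const double VE      = as<double>(cfg["V_E"]);      // mV
  const double VI      = as<double>(cfg["V_I"]);      // mV
  const double taudE   = as<double>(cfg["tau_dE"]);   // ms
  const double taudI   = as<double>(cfg["tau_dI"]);   // ms
  const double wEP     = as<double>(cfg["w_EP_mV"]);  // mV jump per Poisson spike
  const double lamP    = as<double>(cfg["poisson_rate_per_step"]); // expected unit spikes/step
  const int    nP      = as<int>(cfg["N_P"]);
  // inhibitory STDP (Vogels-Sprekeler rule on I->E conductances)
  const int    stdp_steps = as<int>(cfg["stdp_steps"]); // plastic while t < stdp_steps
  const double eta     = as<double>(cfg["eta"]);
  const double alpha   = as<double>(cfg["alpha"]);
  const double g0EI    = as<double>(cfg["g0_EI"]);
  const double tauSTDP = as<double>(cfg["tau_STDP"]);

  // --- network --------------------------------------------------------------
  const int n = as<int>(net["n"]);
  IntegerVector e_ptr = net["e_ptr"], e_tgt = net["e_tgt"];
  NumericVector e_w   = net["e_w"];
  IntegerVector i_ptr = net["i_ptr"], i_tgt = net["i_tgt"];
  NumericVector i_w   = net["i_w"];
  IntegerVector p_ptr = net["p_ptr"], p_tgt = net["p_tgt"];
  NumericVector p_w   = clone(as<NumericVector>(net["p_w"]));
  IntegerVector c_ptr = net["c_ptr"], c_src = net["c_src"], c_idx = net["c_idx"];
  IntegerVector q_ptr = net["q_ptr"], q_tgt = net["q_tgt"];

  // --- initial state --------------------------------------------------------
  std::vector<double> V  = as<std::vector<double> >(proto["V0"]);
  std::vector<double> gE = as<std::vector<double> >(proto["gE0"]);
  std::vector<double> gI = as<std::vector<double> >(proto["gI0"]);
  std::vector<double> x  = as<std::vector<double> >(proto["x0_trace"]);
  std::vector<int> refr(n, 0);

  IntegerVector stim_steps   = proto["stim_steps"];    // 0-based, sorted
  IntegerVector stim_neurons = proto["stim_neurons"];  // 0-based
  const int rec_from   = as<int>(proto["record_spikes_from"]);
  const int vrec_every = as<int>(proto["vrec_every"]);
  const int vrec_from  = as<int>(proto["vrec_from"]);
  const int vrec_to    = as<int>(proto["vrec_to"]);
  IntegerVector vrec_ids = proto["vrec_ids"];

  const int delay = (int) std::lround(taul / dt);
  if (delay < 1) stop("synaptic latency must be at least one time step");
  const int refr_steps = (int) std::ceil(taurefr / dt);
  const double dE = std::exp(-dt / taudE);
  const double dI = (taudI > 0) ? std::exp(-dt / taudI) : 0.0;
  const double dS = (tauSTDP > 0) ? std::exp(-dt / tauSTDP) : 0.0;
  const double dt_over_C = dt / Cm;

  std::vector<std::vector<int> > ring(delay + 1);
  std::vector<int> spikers;
  spikers.reserve(256);
  const bool has_inh = (i_tgt.size() > 0) || (p_tgt.size() > 0);
  const bool has_stdp = (stdp_steps > 0);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<double> vsamp;
  const int nvrec = vrec_ids.size();

  int stim_i = 0;
  const int nstim = stim_steps.size();

  for (int t = 0; t < nsteps; ++t) {
    // 1. deliver spikes emitted delay steps ago
    std::vector<int> &slot = ring[t % (delay + 1)];
    for (size_t s = 0; s < slot.size(); ++s) {
      const int src = slot[s];
      for (int e = e_ptr[src]; e < e_ptr[src + 1]; ++e) gE[e_tgt[e]] += e_w[e];
      for (int e = i_ptr[src]; e < i_ptr[src + 1]; ++e) gI[i_tgt[e]] += i_w[e];
      for (int e = p_ptr[src]; e < p_ptr[src + 1]; ++e) gI[p_tgt[e]] += p_w[e];
    }
    slot.clear();

    // 2. Poisson delta-current drive (stationary; delivered without delay)
    if (lamP > 0.0 && nP > 0) {
      const int ns = (int) R::rpois(lamP);
      for (int s = 0; s < ns; ++s) {
        int unit = (int) (unif_rand() * nP);
        if (unit >= nP) unit = nP - 1;
        for (int e = q_ptr[unit]; e < q_ptr[unit + 1]; ++e) {
          const int j = q_tgt[e];
          if (refr[j] == 0) V[j] += wEP;
        }
      }
    }

    // 3. integrate membrane, decay conductances/traces, detect crossings
    spikers.clear();
    if (has_inh) {
      for (int j = 0; j < n; ++j) {
        if (refr[j] > 0) {
          --refr[j];
          V[j] = Vrest;
        } else {
          V[j] += dt_over_C * (gleak * (Vrest - V[j]) + gE[j] * (VE - V[j])
                               + gI[j] * (VI - V[j]) + Ibg);
          if (V[j] >= Vthr) spikers.push_back(j);
        }
        gE[j] *= dE;
        gI[j] *= dI;
        if (has_stdp) x[j] *= dS;
      }
    } else {
      for (int j = 0; j < n; ++j) {
        if (refr[j] > 0) {
          --refr[j];
          V[j] = Vrest;
        } else {
          V[j] += dt_over_C * (gleak * (Vrest - V[j]) + gE[j] * (VE - V[j]) + Ibg);
          if (V[j] >= Vthr) spikers.push_back(j);
        }
        gE[j] *= dE;
      }
    }

    // 4. external stimulation: force the first assembly to fire this step
    //    (equivalent to setting the membrane potential to threshold)
    if (stim_i < nstim && stim_steps[stim_i] == t) {
      for (int s = 0; s < stim_neurons.size(); ++s) {
        const int j = stim_neurons[s];
        bool already = false;
        for (size_t u = 0; u < spikers.size(); ++u)
          if (spikers[u] == j) { already = true; break; }
        if (!already) {
          V[j] = Vthr;
          refr[j] = 0;
          spikers.push_back(j);
        }
      }
      ++stim_i;
    }

    if (!spikers.empty()) {
      const bool plastic = (t < stdp_steps);
      if (plastic) {
        // pre-rule first, then post-rule; traces read before this step's increments
        for (size_t s = 0; s < spikers.size(); ++s) {
          const int k = spikers[s];
          for (int e = p_ptr[k]; e < p_ptr[k + 1]; ++e) {
            p_w[e] += eta * g0EI * (x[p_tgt[e]] - alpha);
            if (p_w[e] < 0.0) p_w[e] = 0.0;
          }
        }
        for (size_t s = 0; s < spikers.size(); ++s) {
          const int j = spikers[s];
          for (int e = c_ptr[j]; e < c_ptr[j + 1]; ++e) {
            const int w = c_idx[e];
            p_w[w] += eta * g0EI * x[c_src[e]];
            if (p_w[w] < 0.0) p_w[w] = 0.0;
          }
        }
      }
      std::vector<int> &dest = ring[(t + delay) % (delay + 1)];
      for (size_t s = 0; s < spikers.size(); ++s) {
        const int j = spikers[s];
        if (stdp_steps > 0) x[j] += 1.0;
        V[j] = Vrest;
        refr[j] = refr_steps;
        dest.push_back(j);
        if (t >= rec_from) {
          spike_t.push_back(t * dt);
          spike_id.push_back(j);
        }
      }
    }

    // 6. membrane-potential sampling
    if (vrec_every > 0 && t >= vrec_from && t < vrec_to
        && (t - vrec_from) % vrec_every == 0) {
      for (int s = 0; s < nvrec; ++s) vsamp.push_back(V[vrec_ids[s]]);
    }

    if ((t & 0x03FF) == 0) {
      Rcpp::checkUserInterrupt();
      for (int j = 0; j < n; ++j)
        if (!std::isfinite(V[j]))
          stop("numerical instability: non-finite membrane potential (neuron %d, step %d)",
               j + 1, t);
    }
  }

  NumericMatrix vmat(nvrec, nvrec > 0 ? (int) (vsamp.size() / nvrec) : 0);
  std::copy(vsamp.begin(), vsamp.end(), vmat.begin());

  return List::create(
    _["spike_t"]  = NumericVector(spike_t.begin(), spike_t.end()),
    _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["V"]  = NumericVector(V.begin(), V.end()),
    _["gE"] = NumericVector(gE.begin(), gE.end()),
    _["gI"] = NumericVector(gI.begin(), gI.end()),
    _["x_trace"] = NumericVector(x.begin(), x.end()),
    _["p_w"] = p_w,
    _["V_samples"] = vmat);
}
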