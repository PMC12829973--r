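# replaynet

Conditions for replay of neuronal assembly sequences: spiking-network
simulation and an analytically tractable population model.

## The problem

A stored sequence of neuronal assemblies (groups of `M` neurons with
strengthened mutual connections) is *replayed* when stimulating the first
assembly makes every assembly fire once, in order, down to the last one.
Whether that happens depends on the interplay of feedforward connectivity
across assemblies (probability `p_f`, summed weight `F = M p_f w_EE`) and
recurrent connectivity within them (`p_r`, `R = M p_r w_EE`): weak
feedforward drive can be rescued by recurrent amplification, producing
slower, wider activity pulses. `replaynet` is for computational
neuroscientists who want to simulate these dynamics and test the analytical
conditions that predict them.

The package provides:

* **Spiking simulator** (`networkConfig`, `buildConnectome`,
  `runReplayTrial`, `runBalancing`): clocked LIF networks with conductance
  synapses, delayed spike delivery, inhibitory STDP balancing and Poisson
  background drive, in three variants — EI assemblies, global inhibition,
  and a minimal excitatory-only network — plus leak-free / fixed-in-degree
  / manual-membrane-initialization test modes. The core loop is compiled
  (Rcpp) and fully seed-deterministic.
* **Replay metrics** (`detectReplay`, `measurePulse`, `scanGrid`): peak
  detection on Gaussian-smoothed assembly rates, success criteria (ordered
  peaks above 30 spk/s, spike counts within 90–110% of `M`, quiet
  background), failure classification, pulse FWHM and speed, and
  reproducible connectivity-grid scans.
* **Population model** (`runPopulationReplay`): time-discrete dynamics of
  each assembly's membrane-potential distribution (rectangle or clipped
  Gaussian), `x_t = x_{t-1} + R a_{t-1} + F a'_{t-1} + J_t`.
* **Theory** (`linearEstimate`, `estimateSpeed`, `asymptoticSpeedCondition`,
  `minFeedforwardForSpeed`): the closed-form linear estimate
  `x̂_t = J (F/U)^{i-1} Σ_k C(k-1, i-1) (R/U)^{k-i}`, the necessary
  conditions `R + F > U − x0` and `F > −x0`, and the asymptotic
  speed–connectivity bound
  `F/U ≥ S ((1−S)/(R/U))^{1/S−1}` (for `R/U > 1−S`).
* **Mapping** (`mapSpikingParams`, `predictedSpeedBorder`,
  `minAssemblySize`): conversion between spiking parameters and
  population-model coordinates (`w_EE ≈ g_EE τ_dE (V_E − μ)/C`,
  `u = U/(M w_EE)`, `Δt ≈ τ_l + 1.8 ms`, `S = s Δt`).
* **Workbench** (`experimentPlan`, `runExperiment`, `inst/cli/replaynet`):
  scripted, hash-stamped regeneration of the phase-diagram experiments and
  a thin command-line front end.

## Worked example

Replay in the minimal excitatory-only model (5,000 neurons, 10 assemblies
of 500) at `p_f = 14 %`, `p_r = 0`:

```r
library(replaynet)
cfg <- networkConfig("minimal")            # reference parameters, tau_l = 1 ms
cn  <- buildConnectome(cfg, p_r = 0, p_f = 0.14, seed = 7)
rec <- runReplayTrial(cn, seed = 3)        # 1 s warm-up, stimulate assembly 1
detectReplay(rec)
#> <replay_outcome> success; speed 0.497 assemblies/ms, FWHM 4.96 ms
```

The pulse traverses one assembly every ~2 ms (0.5 assemblies/ms, the
fastest the 1 ms synaptic latency allows) with a ~5 ms full width at half
maximum. The population model predicts the corresponding regime: with
`w_EE = 0.051 mV`, `F = 500 × 0.14 × 0.051 = 3.57 mV` exceeds the
distribution width `U ≈ 2 mV`, so propagation at one assembly per synaptic
time step needs no recurrence:

```r
mp <- mapSpikingParams(cfg, p_r = 0, p_f = 0.14)   # mu = -51 mV, sigma = 0.5 mV
c(F_mV = mp$F, U_mV = mp$U, Delta_t = mp$Delta_t)
#>    F_mV    U_mV Delta_t
#>    3.57    2.00    2.82
tr <- runPopulationReplay(populationParams(R = 0, F = 1, U = 1, J = 1, q = 10))
tr$S
#> [1] 1
```

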