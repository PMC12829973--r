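test_that("configurations validate and expose the membrane time constant", {
  cfg <- networkConfig("minimal")
  expect_equal(cfg$C / cfg$g_leak, 20)
  expect_error(networkConfig("minimal", M = 600L, q = 10L), "N_E")
  expect_error(networkConfig("minimal", p_EP = 1.5), "probabilities")
  lf <- networkConfig("minimal", leak_free = TRUE)
  expect_equal(lf$g_leak, 0)
  expect_equal(lf$I_bg, 0)
  expect_equal(lf$N_P, 0L)
})

test_that("YAML round trip preserves configuration overrides", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(variant = "minimal", tau_l = 4, N_E = 120L,
                        M = 40L, q = 3L, N_P = 100L), f)
  cfg <- readNetworkConfig(f)
  expect_s3_class(cfg, "network_config")
  expect_equal(cfg$tau_l, 4)
  expect_equal(cfg$N_E, 120L)
})

test_that("connectome sampling honors mode, probabilities and feasibility", {
  cfg <- tiny_minimal_config()
  # no sequence synapses at zero probability
  cn0 <- buildConnectome(cfg, 0, 0, seed = 1)
  expect_equal(length(cn0$exc$tgt), 0L)
  # fixed in-degree: every sequence neuron receives exactly round(M p) afferents
  cfgF <- tiny_minimal_config(connectivity_mode = "fixed_in_degree")
  cnF <- buildConnectome(cfgF, 0.1, 0.2, seed = 2)
  expect_true(all(sequenceInDegree(cnF, "recurrent") == 4L))    # 40 * 0.1
  expect_true(all(sequenceInDegree(cnF, "feedforward") == 8L))  # 40 * 0.2
  expect_error(buildConnectome(cfgF, 1, 0, seed = 3), "infeasible")
  # Bernoulli: in-degree mean M p with binomial spread
  cfgB <- networkConfig("minimal", N_E = 1000L, M = 500L, q = 2L,
                        N_P = 100L, nu_P = 50, p_EP = 0.01)
  cnB <- buildConnectome(cfgB, 0, 0.08, seed = 4)
  deg <- sequenceInDegree(cnB, "feedforward")
  expect_equal(mean(deg), 500 * 0.08, tolerance = 0.05)
  expect_equal(stats::sd(deg), sqrt(500 * 0.08 * 0.92), tolerance = 0.2)
})

test_that("identical seeds reproduce connectomes and spike records exactly", {
  cfg <- tiny_minimal_config()
  cn1 <- buildConnectome(cfg, 0.1, 0.2, seed = 5)
  cn2 <- buildConnectome(cfg, 0.1, 0.2, seed = 5)
  expect_identical(cn1$exc, cn2$exc)
  r1 <- runReplayTrial(cn1, seed = 9, warmup_ms = 100, horizon_ms = 100)
  r2 <- runReplayTrial(cn2, seed = 9, warmup_ms = 100, horizon_ms = 100)
  expect_identical(r1$events, r2$events)
  cn3 <- buildConnectome(cfg, 0.1, 0.2, seed = 6)
  expect_false(identical(cn1$exc, cn3$exc))
})

test_that("membrane relaxes to rest with the leak time constant", {
  cfg <- networkConfig("minimal", N_E = 3L, M = 1L, q = 3L, N_P = 0L, I_bg = 0)
  cn <- buildConnectome(cfg, 0, 0, seed = 1)
  st <- newSimState(cn, V = -55)
  out <- stepNetwork(cn, st, n_steps = 200)  # 20 ms
  # forward Euler of dV/dt = -(V - Vrest)/tau_m: (1 - dt/20)^n
  expect_equal(out$state$V[1], -60 + 5 * (1 - 0.1 / 20)^200, tolerance = 1e-10)
  expect_equal(out$state$V[1], -60 + 5 * exp(-1), tolerance = 0.01)
  # leak-free: the membrane holds its value indefinitely
  cfgL <- networkConfig("minimal", N_E = 3L, M = 1L, q = 3L, leak_free = TRUE)
  cnL <- buildConnectome(cfgL, 0, 0, seed = 1)
  outL <- stepNetwork(cnL, newSimState(cnL, V = -55), n_steps = 5000)
  expect_true(all(outL$state$V == -55))
})

test_that("conductances decay exponentially to machine precision", {
  cfg <- networkConfig("minimal", N_E = 2L, M = 1L, q = 2L, N_P = 0L, I_bg = 0)
  cn <- buildConnectome(cfg, 0, 0, seed = 1)
  st <- newSimState(cn)
  st$gE <- rep(1.5, cn$n)
  out <- stepNetwork(cn, st, n_steps = 137)
  expect_equal(out$state$gE, rep(1.5 * exp(-137 * 0.1 / 2), cn$n),
               tolerance = 1e-13)
})

test_that("Poisson delta synapses move the membrane on an exact jump lattice", {
  # no leak, no constant current: V can only change by w_EP per delivery
  cfg <- networkConfig("minimal", N_E = 60L, M = 20L, q = 3L, g_leak = 0,
                       I_bg = 0, N_P = 50L, nu_P = 200, p_EP = 0.2,
                       V_thr = 0)  # threshold far away: no spikes
  cn <- buildConnectome(cfg, 0, 0, seed = 3)
  out <- stepNetwork(cn, newSimState(cn), n_steps = 500)
  k <- (out$state$V - cfg$V_rest) / (cfg$w_EP / 1000)
  expect_true(all(abs(k - round(k)) < 1e-9))
  expect_gt(sum(k), 0)
})

test_that("refractoriness separates successive spikes of a neuron", {
  cfg <- tiny_minimal_config(I_bg = 250)  # strong drive: tonic firing
  cn <- buildConnectome(cfg, 0.5, 0.5, seed = 8)
  rec <- runReplayTrial(cn, seed = 2, warmup_ms = 200, horizon_ms = 150)
  ev <- rec$events
  isi <- unlist(lapply(split(ev$time_ms, ev$neuron), function(tt)
    if (length(tt) > 1) diff(sort(tt)) else numeric(0)))
  expect_gt(length(isi), 50)  # the regime does produce repeated firing
  expect_true(all(isi >= cfg$tau_refr - 1e-9))
})

test_that("deterministic cascade matches the closed-form conductance solution", {
  # sigma = 0, leak-free, fixed in-degree: every neuron of assembly 2 receives
  # exactly k synchronous inputs and crosses threshold at the analytic time
  cfg <- networkConfig("minimal", N_E = 30L, M = 10L, q = 3L,
                       leak_free = TRUE, connectivity_mode = "fixed_in_degree",
                       g_EE = 0.5)
  cn <- buildConnectome(cfg, 0, 1, seed = 4)  # k = 10 feedforward afferents
  st <- initMembraneGaussian(cn, mu = -51, sigma = 0, seed = 1)
  rec <- runReplayTrial(cn, seed = 1, state = st, warmup_ms = 0, horizon_ms = 50)
  ev <- rec$events
  t_by_assembly <- lapply(1:3, function(i)
    sort(ev$time_ms[cn$assembly[ev$neuron] == i]))
  # all M neurons of each assembly fire, synchronously within an assembly
  for (i in 1:3) {
    expect_length(t_by_assembly[[i]], 10L)
    expect_equal(diff(range(t_by_assembly[[i]])), 0)
  }
  # dV/dt = G0 exp(-t/tau_d)(VE - V)/C from V0 = -51 crosses -50 at
  # t_c = -tau_d log(1 - (C / (G0 tau_d)) log((VE-V0)/(VE-thr)))
  G0 <- 10 * 0.5
  t_c <- -2 * log(1 - (200 / (G0 * 2)) * log(51 / 50))
  lag <- cfg$tau_l + t_c
  gaps <- diff(vapply(t_by_assembly, function(x) x[1], numeric(1)))
  expect_equal(gaps, rep(lag, 2), tolerance = 0.15)  # within Euler resolution
})

test_that("inhibitory STDP applies the pre- and post-spike rules", {
  # one E cell (silent), one I cell forced to fire once: lone presynaptic
  # spike depresses by eta * g0 * alpha with alpha = 2 nu_0 tau_STDP = 0.04
  cfg <- networkConfig("global_inhibition", N_E = 2L, N_I = 1L, M = 1L, q = 2L,
                       p_bg = 0, p_IE = 0, p_II = 0, p_EI = 1, I_bg = 0)
  cn <- buildConnectome(cfg, 0, 0, seed = 1)
  expect_equal(length(cn$plastic$tgt), 2L)  # I -> both E cells
  st <- newSimState(cn)
  st$V[3] <- -49.5  # I neuron above threshold: fires at the first step
  set.seed(1)
  out <- replaynet:::.run_core(cn, st, 200, stdp_steps = 200L)
  expect_equal(out$state$p_w, rep(0.4 - 0.01 * 0.4 * 0.04, 2), tolerance = 1e-12)
  # a later postsynaptic spike potentiates by eta * g0 * x_I (decayed trace)
  st2 <- newSimState(cn)
  st2$V[3] <- -49.5
  set.seed(1)
  out2 <- replaynet:::.run_core(cn, st2, 200, stim_steps = 40L,
                                stim_neurons = 1L, stdp_steps = 200L)
  x_I <- exp(-40 * 0.1 / 20)  # trace of the I spike, decayed over 40 steps
  expect_equal(out2$state$p_w[1], 0.4 - 0.01 * 0.4 * 0.04 + 0.01 * 0.4 * x_I,
               tolerance = 1e-9)
  expect_error(runBalancing(buildConnectome(tiny_minimal_config(), 0, 0, 1)),
               "no inhibitory synapses")
})

test_that("STDP balancing steers the excitatory rate toward its target", {
  cfg <- small_glob_config()
  cn <- buildConnectome(cfg, 0.1, 0.1, seed = 2)
  st <- runBalancing(cn, duration_ms = 5000, seed = 3)
  expect_false(identical(st$p_w, cn$plastic$w))
  set.seed(4)
  out <- replaynet:::.run_core(cn, st, 20000)
  rate <- sum(out$spikes$neuron <= cfg$N_E) / cfg$N_E / 2
  expect_gt(rate, 0.1)   # not silent
  expect_lt(rate, 10)    # nor runaway: near the 1 spk/s target
})

test_that("manual membrane draws land in the clipped range with recorded coordinates", {
  cfg <- networkConfig("minimal", N_E = 120L, M = 40L, q = 3L, leak_free = TRUE)
  cn <- buildConnectome(cfg, 0, 0.2, seed = 1)
  st <- initMembraneGaussian(cn, mu = -51, sigma = 0.5, seed = 7)
  expect_true(all(st$V >= -52 & st$V <= -50))
  expect_equal(attr(st, "U"), 2)
  expect_equal(attr(st, "x0"), 0)
  st2 <- initMembraneGaussian(cn, mu = -52.9, sigma = 1, seed = 7)
  expect_equal(attr(st2, "U"), 4)
  expect_equal(attr(st2, "x0"), -0.9)
  st0 <- initMembraneGaussian(cn, mu = -51, sigma = 0, seed = 7)
  expect_true(all(st0$V == -51))
  expect_error(initMembraneGaussian(cn, -51, -1), "non-negative")
})

test_that("spike records round-trip through CSV + JSON", {
  cfg <- tiny_minimal_config()
  cn <- buildConnectome(cfg, 0.1, 0.3, seed = 5)
  rec <- runReplayTrial(cn, seed = 2, warmup_ms = 100, horizon_ms = 80)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  writeSpikeRecord(rec, csv, js)
  back <- readSpikeRecord(csv, js)
  expect_equal(back$events$time_ms, rec$events$time_ms)
  expect_equal(back$events$neuron, rec$events$neuron)
  expect_equal(back$assembly, rec$assembly)
  expect_equal(back$config$tau_l, rec$config$tau_l)
})
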