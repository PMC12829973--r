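# Small network configurations and synthetic spike records used across tests.

tiny_minimal_config <- function(...) {
  networkConfig("minimal", N_E = 120L, M = 40L, q = 3L,
                N_P = 500L, nu_P = 50, p_EP = 0.05, ...)
}

small_glob_config <- function(...) {
  networkConfig("global_inhibition", N_E = 800L, N_I = 200L, M = 50L, q = 5L,
                p_IE = 0.2, p_II = 0.2, p_EI = 0.2, p_bg = 0.05, ...)
}

# A hand-built spike record: `spikes_per_assembly[i]` spikes for assembly i,
# peaked at stim + i * spacing_ms with the given jitter.
synthetic_record <- function(spikes_per_assembly, q = 10L, M = 500L,
                             spacing_ms = 2, jitter_ms = 0.3,
                             stim_ms = 0, horizon_ms = 300,
                             n_bg = 0L, tau_l = 1, seed = 1L) {
  set.seed(seed)
  n <- q * M + n_bg
  assembly <- c(rep(seq_len(q), each = M), rep(0L, n_bg))
  ev <- do.call(rbind, lapply(seq_len(q), function(i) {
    k <- spikes_per_assembly[i]
    if (k == 0L) return(NULL)
    ids <- (i - 1L) * M + (((seq_len(k) - 1L) %% M) + 1L)
    data.frame(time_ms = stim_ms + i * spacing_ms +
                 stats::rnorm(k, 0, jitter_ms),
               neuron = ids)
  }))
  if (is.null(ev)) ev <- data.frame(time_ms = numeric(0), neuron = integer(0))
  ev <- ev[order(ev$time_ms), ]
  rownames(ev) <- NULL
  cfg <- networkConfig("minimal", N_E = max(n, q * M), M = M, q = q,
                       tau_l = tau_l)
  structure(list(events = ev, assembly = assembly,
                 is_inh = rep(FALSE, n), n = n, M = M, q = q,
                 stim_time_ms = stim_ms, horizon_ms = horizon_ms,
                 config = cfg, p_r = NA_real_, p_f = NA_real_, seed = seed),
            class = "spike_record")
}

# independent naive evaluation of the linearized rectangle-model solution
naive_linear_estimate <- function(i, t, J, R, F, U = 1) {
  if (t < i) return(0)
  k <- i:t
  J * (F / U)^(i - 1) * sum(choose(k - 1, i - 1) * (R / U)^(k - i))
}
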