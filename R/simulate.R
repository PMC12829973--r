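.na0 <- function(x, default = 0) if (is.null(x) || is.na(x)) default else x

# scalar configuration list handed to the C++ core
.sim_cfg <- function(cfg, n_steps, stdp_steps = 0L) {
  nu0_per_ms <- .na0(cfg$nu_0) / 1000
  list(dt = cfg$dt, n_steps = as.integer(n_steps),
       C = cfg$C, g_leak = cfg$g_leak, V_rest = cfg$V_rest, V_thr = cfg$V_thr,
       tau_refr = cfg$tau_refr, tau_l = cfg$tau_l, I_bg = cfg$I_bg,
       V_E = cfg$V_E, V_I = .na0(cfg$V_I, -80),
       tau_dE = cfg$tau_dE, tau_dI = .na0(cfg$tau_dI, 1),
       w_EP_mV = .na0(cfg$w_EP) / 1000,  # table stores uV
       poisson_rate_per_step = .na0(cfg$N_P) * .na0(cfg$nu_P) * cfg$dt / 1000,
       N_P = as.integer(.na0(cfg$N_P)),
       stdp_steps = as.integer(stdp_steps),
       eta = .na0(cfg$eta), alpha = 2 * nu0_per_ms * .na0(cfg$tau_STDP),
       g0_EI = .na0(cfg$g0_EI), tau_STDP = .na0(cfg$tau_STDP))
}

# 0-based network arrays for the C++ core
.sim_net <- function(cn) {
  list(n = cn$n,
       e_ptr = cn$exc$ptr, e_tgt = cn$exc$tgt - 1L, e_w = cn$exc$w,
       i_ptr = cn$inh$ptr, i_tgt = cn$inh$tgt - 1L, i_w = cn$inh$w,
       p_ptr = cn$plastic$ptr, p_tgt = cn$plastic$tgt - 1L, p_w = cn$plastic$w,
       c_ptr = cn$plastic$cptr, c_src = cn$plastic$csrc - 1L,
       c_idx = cn$plastic$cidx - 1L,
       q_ptr = cn$poisson$ptr, q_tgt = cn$poisson$tgt - 1L)
}

#' Fresh simulator state for a connectome
#'
#' Membrane potentials start at the resting potential (or a supplied vector),
#' conductances and STDP traces at zero, plastic weights at their current
#' values in the connectome.
#'
#' @param connectome A \code{"connectome"}.
#' @param V Initial membrane potentials (scalar or length-n vector, mV).
#' @return An object of class \code{"sim_state"}.
#' @export
newSimState <- function(connectome, V = connectome$config$V_rest) {
  n <- connectome$n
  structure(list(V = rep_len(V, n), gE = numeric(n), gI = numeric(n),
                 x_trace = numeric(n), p_w = connectome$plastic$w),
            class = "sim_state")
}

# single entry point into the compiled core
.run_core <- function(cn, state, n_steps, stim_steps = integer(0),
                      stim_neurons = integer(0), record_spikes_from = 0L,
                      vrec_every = 0L, vrec_from = 0L, vrec_to = 0L,
                      vrec_ids = integer(0), stdp_steps = 0L) {
  cfg <- .sim_cfg(cn$config, n_steps, stdp_steps)
  net <- .sim_net(cn)
  net$p_w <- state$p_w
  proto <- list(V0 = state$V, gE0 = state$gE, gI0 = state$gI,
                x0_trace = state$x_trace,
                stim_steps = as.integer(stim_steps),
                stim_neurons = as.integer(stim_neurons) - 1L,
                record_spikes_from = as.integer(record_spikes_from),
                vrec_every = as.integer(vrec_every),
                vrec_from = as.integer(vrec_from),
                vrec_to = as.integer(vrec_to),
                vrec_ids = as.integer(vrec_ids) - 1L)
  out <- lif_simulate(cfg, net, proto)
  list(state = structure(list(V = out$V, gE = out$gE, gI = out$gI,
                              x_trace = out$x_trace, p_w = out$p_w),
                         class = "sim_state"),
       spikes = data.frame(time_ms = out$spike_t, neuron = out$spike_id + 1L),
       V_samples = out$V_samples)
}

#' Advance the network by a number of integration steps
#'
#' Clocked update at \code{dt}: delayed synaptic deliveries, Poisson drive,
#' forward-Euler membrane integration, exact exponential conductance decay,
#' threshold/reset/refractoriness. Intended for short, inspectable runs
#' (unit-level checks of the integration); full protocols should use
#' \code{\link{runReplayTrial}}, which keeps delayed spikes and refractory
#' clocks inside a single call. Chained \code{stepNetwork} calls do not carry
#' spikes still in the delay line across the call boundary.
#'
#' @param connectome A \code{"connectome"}.
#' @param state A \code{"sim_state"} (default: fresh).
#' @param n_steps Number of dt-steps to run.
#' @return A list with the updated \code{state} and the emitted \code{spikes}
#'   (data frame time_ms, neuron).
#' @export
stepNetwork <- function(connectome, state = NULL, n_steps = 1L) {
  if (is.null(state)) state <- newSimState(connectome)
  out <- .run_core(connectome, state, n_steps)
  out[c("state", "spikes")]
}

#' Balance a network into the asynchronous-irregular state via inhibitory STDP
#'
#' Runs the network with the I-to-E plasticity rule active: near-coincident
#' pre/post firing potentiates a synapse, lone presynaptic spikes depress it
#' by the bias \code{alpha = 2 nu_0 tau_STDP}, steering excitatory cells
#' toward the target rate \code{nu_0}. After \code{duration_ms} the weights
#' are frozen in the returned state.
#'
#' @param connectome A \code{"connectome"} of a variant with inhibition.
#' @param duration_ms Plasticity duration (default 5000 ms).
#' @param seed Integer seed.
#' @param state Optional starting \code{"sim_state"}.
#' @return A \code{"sim_state"} with the balanced (frozen) I->E weights.
#' @export
runBalancing <- function(connectome, duration_ms = 5000, seed = 1L, state = NULL) {
  cfg <- connectome$config
  if (cfg$model_variant == "minimal")
    stop("the minimal variant has no inhibitory synapses to balance")
  if (is.null(state)) state <- newSimState(connectome)
  set.seed(seed)
  n_steps <- round(duration_ms / cfg$dt)
  .run_core(connectome, state, n_steps, stdp_steps = n_steps)$state
}

#' Draw membrane potentials from a clipped Gaussian
#'
#' Initializes every neuron's membrane potential from a Gaussian with mean
#' \code{mu} and SD \code{sigma}, truncated at two SDs around the mean (the
#' same shape as the population model's clipped-Gaussian distribution). In
#' population-model coordinates this realizes a distribution of width
#' \code{U = 4 sigma} whose right edge sits at \code{x0 = mu + 2 sigma -
#' V_thr} relative to the firing threshold; both are recorded as attributes.
#'
#' @param connectome A \code{"connectome"} (typically leak-free,
#'   fixed-in-degree).
#' @param mu Mean (mV).
#' @param sigma SD (mV), >= 0. \code{sigma = 0} sets every potential to
#'   \code{mu}.
#' @param seed Integer seed.
#' @return A \code{"sim_state"} with attributes \code{U} and \code{x0} (mV).
#' @export
initMembraneGaussian <- function(connectome, mu, sigma, seed = 1L) {
  if (sigma < 0) stop("'sigma' must be non-negative")
  set.seed(seed)
  n <- connectome$n
  V <- if (sigma == 0) rep(mu, n) else {
    u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
    mu + sigma * stats::qnorm(u)
  }
  st <- newSimState(connectome, V = V)
  attr(st, "U") <- 4 * sigma
  attr(st, "x0") <- mu + 2 * sigma - connectome$config$V_thr
  st
}

.make_record <- function(cn, events, stim_time_ms, horizon_ms, seed) {
  structure(list(events = events, assembly = cn$assembly,
                 is_inh = cn$is_inh, n = cn$n, M = cn$config$M,
                 q = cn$config$q, stim_time_ms = stim_time_ms,
                 horizon_ms = horizon_ms,
                 config = cn$config, p_r = cn$p_r, p_f = cn$p_f,
                 seed = as.integer(seed)),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %s, %d events, stim at %g ms (horizon %g ms), seed %d\n",
              x$config$model_variant, nrow(x$events), x$stim_time_ms,
              x$horizon_ms, x$seed))
  invisible(x)
}

#' Run replay trials: stimulate the first assembly and record spikes
#'
#' After a warm-up that lets the network settle into its baseline state, all
#' neurons of the first assembly are made to fire simultaneously by setting
#' their membrane potential to the firing threshold; the simulation then runs
#' for \code{horizon_ms}. With \code{n_trials > 1}, trials are separated by
#' \code{inter_trial_ms} of unstimulated activity and all run within a single
#' continuous simulation.
#'
#' @param connectome A \code{"connectome"}.
#' @param seed Integer seed.
#' @param state Optional starting \code{"sim_state"} (e.g. balanced weights
#'   from \code{\link{runBalancing}}, or a manual membrane draw from
#'   \code{\link{initMembraneGaussian}} with \code{warmup_ms = 0}).
#' @param warmup_ms Unstimulated settling time before the first trial.
#' @param horizon_ms Recording window after each stimulation (default 300 ms).
#' @param n_trials Number of stimulations.
#' @param inter_trial_ms Gap between the end of one trial window and the next
#'   stimulation.
#' @return A \code{"spike_record"} (or a list of them when
#'   \code{n_trials > 1}), each holding the events inside its trial window
#'   with times relative to simulation start.
#' @export
runReplayTrial <- function(connectome, seed = 1L, state = NULL,
                           warmup_ms = 1000, horizon_ms = 300,
                           n_trials = 1L, inter_trial_ms = 1000) {
  cn <- connectome
  cfg <- cn$config
  if (is.null(state)) state <- newSimState(cn)
  set.seed(seed)
  dt <- cfg$dt
  period <- horizon_ms + inter_trial_ms
  stim_times <- warmup_ms + (seq_len(n_trials) - 1L) * period
  total_ms <- warmup_ms + (n_trials - 1L) * period + horizon_ms
  stim_steps <- round(stim_times / dt)
  first_assembly <- which(cn$assembly == 1L & !cn$is_inh)
  out <- .run_core(cn, state, round(total_ms / dt),
                   stim_steps = stim_steps, stim_neurons = first_assembly,
                   record_spikes_from = 0L)
  recs <- lapply(seq_len(n_trials), function(k) {
    t0 <- stim_times[k]
    ev <- out$spikes[out$spikes$time_ms >= t0 &
                     out$spikes$time_ms <= t0 + horizon_ms, , drop = FALSE]
    rownames(ev) <- NULL
    .make_record(cn, ev, t0, horizon_ms, seed)
  })
  if (n_trials == 1L) recs[[1L]] else recs
}

#' Sample the baseline membrane-potential distribution
#'
#' Runs the network without stimulation and samples the membrane potentials
#' of all sequence (assembly) excitatory neurons at regular intervals during
#' the recording window, pooling them into one vector. Used to characterize
#' the asynchronous-irregular baseline state.
#'
#' @param connectome A \code{"connectome"}.
#' @param seed Integer seed.
#' @param warmup_ms Settling time before sampling starts.
#' @param record_ms Length of the sampling window.
#' @param sample_every_ms Sampling interval.
#' @return A list: \code{v} (pooled potentials, mV), \code{spikes} (events
#'   during the whole run), \code{state} (final state), \code{rate}
#'   (mean firing rate of sequence neurons during the window, spikes/s).
#' @export
runAIState <- function(connectome, seed = 1L, warmup_ms = 1000,
                       record_ms = 1000, sample_every_ms = 10) {
  cn <- connectome
  cfg <- cn$config
  set.seed(seed)
  dt <- cfg$dt
  seq_E <- which(cn$assembly > 0L & !cn$is_inh)
  n_steps <- round((warmup_ms + record_ms) / dt)
  out <- .run_core(cn, newSimState(cn), n_steps,
                   vrec_every = round(sample_every_ms / dt),
                   vrec_from = round(warmup_ms / dt), vrec_to = n_steps,
                   vrec_ids = seq_E)
  in_win <- out$spikes$time_ms >= warmup_ms &
    out$spikes$neuron %in% seq_E
  rate <- sum(in_win) / length(seq_E) / (record_ms / 1000)
  list(v = as.vector(out$V_samples), spikes = out$spikes,
       state = out$state, rate = rate)
}

#' Fit a Gaussian to pooled membrane potentials
#'
#' Histogram-based nonlinear least-squares fit of a Gaussian profile
#' (amplitude, mean, SD), robust to the clipping of the distribution at the
#' firing threshold and to the small mass near the reset potential; falls
#' back to sample moments if the fit fails to converge.
#'
#' @param v Pooled membrane potentials (mV).
#' @param nbins Number of histogram bins.
#' @return A list with \code{mean}, \code{sd} and \code{method}
#'   (\code{"gaussian_fit"} or \code{"moments"}).
#' @export
fitMembraneGaussian <- function(v, nbins = 80L) {
  h <- graphics::hist(v, breaks = nbins, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$density)
  start <- list(A = max(df$y), m = stats::median(v), s = stats::mad(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - m)^2 / (2 * s^2)), data = df,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mean = mean(v), sd = stats::sd(v), method = "moments"))
  co <- stats::coef(fit)
  list(mean = unname(co["m"]), sd = abs(unname(co["s"])), method = "gaussian_fit")
}

#' Write a spike record to CSV (events) plus a JSON sidecar
#'
#' @param record A \code{"spike_record"}.
#' @param csv Path for the two-column event CSV (time_ms, neuron).
#' @param json Path for the JSON sidecar (assembly map, configuration, seed,
#'   stimulation time), or \code{NULL} to skip.
#' @return Invisibly, \code{record}.
#' @export
writeSpikeRecord <- function(record, csv, json = NULL) {
  utils::write.csv(record$events, csv, row.names = FALSE)
  if (!is.null(json)) {
    side <- list(assembly = record$assembly, is_inh = record$is_inh,
                 n = record$n, M = record$M, q = record$q,
                 stim_time_ms = record$stim_time_ms,
                 horizon_ms = record$horizon_ms,
                 config = record$config[!vapply(record$config, is.null, TRUE)],
                 p_r = record$p_r, p_f = record$p_f, seed = record$seed)
    jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(record)
}

#' Read a spike record written by \code{\link{writeSpikeRecord}}
#'
#' @param csv Path to the event CSV.
#' @param json Path to the JSON sidecar.
#' @return A \code{"spike_record"}.
#' @export
readSpikeRecord <- function(csv, json) {
  ev <- utils::read.csv(csv)
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  cfg <- side$config
  class(cfg) <- "network_config"
  structure(list(events = ev, assembly = as.integer(side$assembly),
                 is_inh = as.logical(side$is_inh), n = side$n, M = side$M,
                 q = side$q, stim_time_ms = side$stim_time_ms,
                 horizon_ms = side$horizon_ms, config = cfg,
                 p_r = side$p_r, p_f = side$p_f, seed = side$seed),
            class = "spike_record")
}
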