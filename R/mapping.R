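#' Effective unitary EPSP of a conductance synapse
#'
#' Estimates how much one presynaptic spike raises the postsynaptic membrane
#' potential: the conductance jump integrates to \code{g_EE * tau_dE}, and at
#' the typical baseline potential \code{mu} the driving force is
#' \code{V_E - mu}, giving \code{w_EE ~ g_EE tau_dE (V_E - mu) / C}. At the
#' default constants this reduces to \code{w_EE ~ -mu * 1e-3} (mV).
#'
#' @param g_EE Conductance jump (nS).
#' @param tau_dE Excitatory decay time constant (ms).
#' @param V_E Excitatory reversal potential (mV).
#' @param mu Baseline membrane potential (mV); the fitted mean of the
#'   asynchronous-irregular distribution, not the resting potential.
#' @param C Membrane capacitance (pF).
#' @return \code{w_EE} in mV.
#' @examples
#' synapticWeightEstimate(0.1, 2, 0, -51, 200)  # 0.051 mV
#' @export
synapticWeightEstimate <- function(g_EE = 0.1, tau_dE = 2, V_E = 0,
                                   mu = -51, C = 200) {
  stopifnot(C > 0)
  g_EE * tau_dE * (V_E - mu) / C
}

#' Population-model connection weights from spiking connectivity
#'
#' \code{R = M p_r w_EE} and \code{F = M p_f w_EE}: the mean summed potential
#' increase an assembly neuron receives from its own assembly / the previous
#' assembly when all of them fire once.
#'
#' @param M Assembly size.
#' @param p_r,p_f Connection probabilities.
#' @param w_EE Unitary EPSP (mV).
#' @return Named vector \code{c(R =, F =)} in mV.
#' @export
connectivityWeights <- function(M, p_r, p_f, w_EE) {
  stopifnot(M >= 1)
  c(R = M * p_r * w_EE, F = M * p_f * w_EE)
}

#' Normalized distribution coordinates and condition borders
#'
#' Expresses the membrane-potential distribution width and offset in
#' connection-probability units: \code{u = U / (M w_EE)} and
#' \code{delta = x0 / (M w_EE)}. In these coordinates the necessary replay
#' conditions become \code{p_r + p_f > u - delta} (total connectivity) and
#' \code{p_f > -delta} (minimum feedforward).
#'
#' @param U Distribution width (mV).
#' @param x0 Right-edge offset from threshold (mV, <= 0).
#' @param M Assembly size.
#' @param w_EE Unitary EPSP (mV).
#' @return A list: \code{u}, \code{delta} (dimensionless fractions),
#'   \code{border_total} (minimal \code{p_r + p_f}), \code{border_ff}
#'   (minimal \code{p_f}).
#' @export
normalizedCoordinates <- function(U, x0, M, w_EE) {
  if (M * w_EE <= 0) stop("M * w_EE must be positive")
  u <- U / (M * w_EE)
  delta <- x0 / (M * w_EE)
  list(u = u, delta = delta, border_total = u - delta, border_ff = -delta)
}

#' Effective synaptic time step of the population model
#'
#' The delay between a presynaptic spike and the centroid of the resulting
#' postsynaptic potential: the synaptic latency plus the harmonic mean of the
#' membrane and synaptic-decay time constants,
#' \code{Delta_t = tau_l + 1 / (1/tau_m + 1/tau_dE)}. Without leak
#' (\code{tau_m = Inf}) this reduces to \code{tau_l + tau_dE}.
#'
#' @param tau_l Synaptic latency (ms).
#' @param tau_m Membrane time constant (ms); may be \code{Inf}.
#' @param tau_dE Excitatory decay time constant (ms).
#' @return \code{Delta_t} in ms.
#' @examples
#' effectiveTimestep(1, 20, 2)  # 1 + 20/11 = 2.818 ms
#' @export
effectiveTimestep <- function(tau_l, tau_m = 20, tau_dE = 2) {
  stopifnot(tau_m > 0, tau_dE > 0)
  tau_l + 1 / (1 / tau_m + 1 / tau_dE)
}

#' Connectivity border sustaining a given replay speed, in spiking units
#'
#' Rescales the asymptotic speed condition to connection probabilities: for a
#' spiking-model speed \code{s} (assemblies/ms) and effective time step
#' \code{Delta_t}, the population-model speed is \code{S = s Delta_t}, and
#' the minimal feedforward probability at each \code{p_r} follows from the
#' two-branch condition with \code{F/U -> p_f/u}, \code{R/U -> p_r/u} (offset
#' \code{delta} shifts the slow-limit branch).
#'
#' @param u Normalized distribution width (fraction, e.g. 0.12).
#' @param delta Normalized offset (fraction, <= 0).
#' @param Delta_t Effective synaptic time step (ms).
#' @param s Spiking replay speed (assemblies/ms); \code{s = 0} gives the
#'   slow-propagation limit \code{p_r + p_f >= u - delta}.
#' @param pr_grid Recurrent probabilities at which to evaluate the border.
#' @return Data frame with \code{p_r} and the minimal \code{p_f}.
#' @export
predictedSpeedBorder <- function(u, delta = 0, Delta_t, s, pr_grid) {
  S <- s * Delta_t
  if (S > 1) stop("infeasible speed: s * Delta_t exceeds one assembly per step")
  pf_min <- minFeedforwardForSpeed(pr_grid, U = u, S = S) - delta
  data.frame(p_r = pr_grid, p_f = pf_min)
}

#' Minimal assembly size for replay
#'
#' Smallest integer \code{M} satisfying the necessary total-connectivity
#' condition \code{M (p_r + p_f) w_EE > U - x0}.
#'
#' @param p_r,p_f Connection probabilities.
#' @param w_EE Unitary EPSP (mV).
#' @param U Distribution width (mV).
#' @param x0 Offset (mV, <= 0).
#' @return Integer \code{M_min}, or \code{NA} when total connectivity is
#'   zero (no finite assembly suffices).
#' @examples
#' minAssemblySize(p_r = 0.09, p_f = 0.09, w_EE = 0.5, U = 10)  # 112
#' @export
minAssemblySize <- function(p_r, p_f, w_EE, U, x0 = 0) {
  tot <- (p_r + p_f) * w_EE
  if (tot <= 0) return(NA_integer_)
  as.integer(floor((U - x0) / tot) + 1L)
}

#' Map spiking-network parameters to population-model quantities
#'
#' Convenience bundle: unitary EPSP, connection weights, normalized
#' coordinates, effective time step, and the speed conversion
#' \code{S = s * Delta_t}.
#'
#' @param config A \code{"network_config"}.
#' @param p_r,p_f Connection probabilities.
#' @param mu,sigma Fitted mean and SD of the baseline membrane-potential
#'   distribution (mV); the distribution width is taken as \code{U = 4 sigma}
#'   with right edge \code{x0 = mu + 2 sigma - V_thr}.
#' @return An object of class \code{"mapped_params"} with fields \code{w_EE},
#'   \code{R}, \code{F}, \code{U}, \code{x0}, \code{u}, \code{delta},
#'   \code{Delta_t}, \code{tau_m}.
#' @export
mapSpikingParams <- function(config, p_r, p_f, mu = -51, sigma = 0.5) {
  cfg <- config
  w_EE <- synapticWeightEstimate(cfg$g_EE, cfg$tau_dE, cfg$V_E, mu, cfg$C)
  U <- 4 * sigma
  x0 <- mu + 2 * sigma - cfg$V_thr
  rf <- connectivityWeights(cfg$M, p_r, p_f, w_EE)
  nc <- normalizedCoordinates(U, x0, cfg$M, w_EE)
  tau_m <- if (cfg$g_leak > 0) cfg$C / cfg$g_leak else Inf
  structure(list(w_EE = w_EE, R = unname(rf["R"]), F = unname(rf["F"]),
                 U = U, x0 = x0, u = nc$u, delta = nc$delta,
                 Delta_t = effectiveTimestep(cfg$tau_l, tau_m, cfg$tau_dE),
                 tau_m = tau_m),
            class = "mapped_params")
}

#' @export
print.mapped_params <- function(x, ...) {
  cat(sprintf("<mapped_params> w_EE = %.4g mV, R = %.3g, F = %.3g mV, U = %.3g mV, x0 = %.3g mV\n",
              x$w_EE, x$R, x$F, x$U, x$x0))
  cat(sprintf("  u = %.3g%%, delta = %.3g%%, Delta_t = %.3g ms (tau_m = %.3g ms)\n",
              100 * x$u, 100 * x$delta, x$Delta_t, x$tau_m))
  invisible(x)
}
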