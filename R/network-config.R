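#' Spiking-network configuration
#'
#' Builds a parameter set for one of the three LIF network variants, with
#' defaults matching the reference parameter table:
#' \describe{
#'   \item{\code{ei_assemblies}}{20,000 E + 5,000 I cells; each assembly holds
#'     M = 500 E and M/4 I cells; background connectivity 1\%; I-to-E synapses
#'     balanced by inhibitory STDP.}
#'   \item{\code{global_inhibition}}{Assemblies are E-only; a homogeneous
#'     inhibitory population connects to/from all E cells with 1\%
#'     probability; same STDP rule.}
#'   \item{\code{minimal}}{E-only, 5,000 cells (= q*M), no background
#'     connections; the asynchronous-irregular baseline comes from a reduced
#'     constant current (58 pA) plus 5,000 external Poisson units at 50
#'     spikes/s connecting with 1\% probability and a 60 uV delta-current
#'     jump.}
#' }
#' Units: mV, ms, nS, pF, pA throughout (so g*V/C has units mV/ms); w_EP is
#' stored in uV as in the parameter table. At defaults the membrane time
#' constant is C/g_leak = 20 ms.
#'
#' @param variant One of \code{"minimal"}, \code{"ei_assemblies"},
#'   \code{"global_inhibition"}.
#' @param leak_free If \code{TRUE}, configures the leak-free test mode used
#'   with manual membrane initialization: \code{g_leak = 0}, \code{I_bg = 0}
#'   and no Poisson drive.
#' @param connectivity_mode \code{"bernoulli"} (each candidate pair connected
#'   independently) or \code{"fixed_in_degree"} (every sequence neuron
#'   receives exactly \code{round(M*p)} afferents per sequence projection).
#' @param ... Named overrides of any default field (e.g. \code{tau_l = 4}).
#' @return An object of class \code{"network_config"}.
#' @examples
#' cfg <- networkConfig("minimal", tau_l = 1)
#' cfg$C / cfg$g_leak  # membrane time constant, ms
#' @export
networkConfig <- function(variant = c("minimal", "ei_assemblies", "global_inhibition"),
                          leak_free = FALSE,
                          connectivity_mode = c("bernoulli", "fixed_in_degree"),
                          ...) {
  variant <- match.arg(variant)
  connectivity_mode <- match.arg(connectivity_mode)
  cfg <- list(
    model_variant = variant,
    N_E = 20000L, N_I = 5000L, M = 500L, q = 10L,
    C = 200, g_leak = 10, V_rest = -60, V_thr = -50,
    tau_refr = 1, tau_l = 1, I_bg = 200, p_bg = 0.01,
    p_IE = NA_real_, p_II = NA_real_, p_EI = NA_real_,
    V_E = 0, V_I = -80,
    g_EE = 0.1, g_IE = 0.1, g_II = 0.4, g0_EI = 0.4,
    tau_dE = 2, tau_dI = 4,
    eta = 0.01, tau_STDP = 20, nu_0 = 1,
    N_P = 0L, nu_P = NA_real_, p_EP = NA_real_, w_EP = NA_real_,
    dt = 0.1,
    connectivity_mode = connectivity_mode,
    leak_free = leak_free)
  if (variant == "global_inhibition") {
    cfg$p_IE <- cfg$p_II <- cfg$p_EI <- 0.01
  } else if (variant == "minimal") {
    cfg$N_E <- 5000L; cfg$N_I <- 0L
    cfg$I_bg <- 58; cfg$p_bg <- 0
    cfg$g_IE <- cfg$g_II <- cfg$g0_EI <- NA_real_
    cfg$V_I <- NA_real_; cfg$tau_dI <- NA_real_
    cfg$eta <- cfg$tau_STDP <- cfg$nu_0 <- NA_real_
    cfg$N_P <- 5000L; cfg$nu_P <- 50; cfg$p_EP <- 0.01; cfg$w_EP <- 60
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (leak_free) {
    cfg$g_leak <- 0
    cfg$I_bg <- 0
    cfg$N_P <- 0L
  }
  validateNetworkConfig(cfg)
  structure(cfg, class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> variant = %s, N_E = %d, N_I = %d, q = %d, M = %d\n",
              x$model_variant, x$N_E, x$N_I, x$q, x$M))
  cat(sprintf("  tau_l = %g ms, dt = %g ms, connectivity = %s%s\n",
              x$tau_l, x$dt, x$connectivity_mode,
              if (x$leak_free) ", leak-free" else ""))
  invisible(x)
}

validateNetworkConfig <- function(cfg) {
  stopifnot(cfg$q >= 1, cfg$M >= 1, cfg$q * cfg$M <= cfg$N_E,
            cfg$C > 0, cfg$g_leak >= 0, cfg$dt > 0,
            cfg$tau_l >= cfg$dt, cfg$tau_dE > 0)
  probs <- c(cfg$p_bg, cfg$p_IE, cfg$p_II, cfg$p_EI, cfg$p_EP)
  probs <- probs[!is.na(probs)]
  if (any(probs < 0 | probs > 1)) stop("connection probabilities must be in [0, 1]")
  invisible(TRUE)
}

#' Read a network configuration from a YAML file
#'
#' The file must name a \code{variant} and may override any configuration
#' field, mirroring the parameter-table field names.
#'
#' @param path Path to a YAML file.
#' @return A \code{"network_config"}.
#' @export
readNetworkConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$variant)) stop("YAML config must contain a 'variant' field")
  variant <- y$variant
  y$variant <- NULL
  lf <- isTRUE(y$leak_free); y$leak_free <- NULL
  mode <- if (is.null(y$connectivity_mode)) "bernoulli" else y$connectivity_mode
  y$connectivity_mode <- NULL
  do.call(networkConfig, c(list(variant = variant, leak_free = lf,
                                connectivity_mode = mode), y))
}
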