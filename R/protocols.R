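#' Locate the connectivity threshold of the minimal spiking model
#'
#' Scans (p_r, p_f) points along and around the p_r = p_f diagonal for each
#' total connectivity in \code{totals} (for a total of k percentage points,
#' the points p_f = ceil(k/2), ceil(k/2)+1, ceil(k/2)+2 with p_r making up
#' the remainder) and reports the smallest total \code{p_r + p_f} at which
#' any point reaches at least 80\% successful replays.
#'
#' @param base_seed Master seed.
#' @param totals Total connectivities to probe (fractions).
#' @param n_networks,n_trials Replications per point.
#' @param tau_l Synaptic latency (ms).
#' @return A list: \code{scan} (the \code{"grid_scan"} data frame) and
#'   \code{min_total_pct} (smallest successful total, in percent).
#' @export
scanConnectivityThreshold <- function(base_seed = 1L,
                                      totals = seq(0.08, 0.16, by = 0.01),
                                      n_networks = 3L, n_trials = 3L,
                                      tau_l = 1) {
  pairs <- do.call(rbind, lapply(totals, function(s) {
    k <- round(s * 100)
    pf <- ceiling(k / 2) + 0:2
    data.frame(p_r = (k - pf) / 100, p_f = pf / 100)
  }))
  pairs <- unique(pairs[pairs$p_r >= 0 & pairs$p_f <= 1, ])
  cfg <- networkConfig("minimal", tau_l = tau_l)
  scan <- scanGrid(cfg, pairs = pairs, n_networks = n_networks,
                   n_trials = n_trials, base_seed = base_seed)
  ok <- scan$success_fraction >= 0.8
  list(scan = scan,
       min_total_pct = if (any(ok)) 100 * min(scan$p_r[ok] + scan$p_f[ok])
                       else NA_real_)
}

#' Speed range of the minimal model at a given synaptic latency
#'
#' Scans a coarse connectivity grid in two regions: a high-feedforward core
#' (p_f 10--16\%, p_r 0--12\%) where the fastest pulses live, and an
#' extension toward the low-connectivity success border (p_f 4--8\%, p_r
#' 6--16\%) where the slowest sustainable pulses live. Reports the maximum
#' mean asymptotic speed over the core and the minimum over all successful
#' points.
#'
#' @param base_seed Master seed.
#' @param tau_l Synaptic latency (ms), default 4.
#' @param n_networks,n_trials Replications per point.
#' @return A list: \code{scan} (with a \code{region} column),
#'   \code{max_speed} and \code{min_speed} (assemblies/ms).
#' @export
scanDelayPanel <- function(base_seed = 1L, tau_l = 4,
                           n_networks = 3L, n_trials = 3L) {
  core <- expand.grid(p_r = seq(0, 0.12, by = 0.02),
                      p_f = seq(0.10, 0.16, by = 0.02),
                      KEEP.OUT.ATTRS = FALSE)
  ext <- expand.grid(p_r = seq(0.06, 0.16, by = 0.02),
                     p_f = seq(0.04, 0.08, by = 0.02),
                     KEEP.OUT.ATTRS = FALSE)
  pairs <- rbind(core, ext)
  cfg <- networkConfig("minimal", tau_l = tau_l)
  scan <- scanGrid(cfg, pairs = pairs, n_networks = n_networks,
                   n_trials = n_trials, base_seed = base_seed)
  scan$region <- rep(c("core", "border_extension"),
                     c(nrow(core), nrow(ext)))
  ok <- scan$success_fraction >= 0.8 & is.finite(scan$speed)
  list(scan = scan,
       max_speed = if (any(ok & scan$region == "core"))
         max(scan$speed[ok & scan$region == "core"]) else NA_real_,
       min_speed = if (any(ok)) min(scan$speed[ok]) else NA_real_)
}

#' Gaussian fit of the baseline membrane-potential distribution
#'
#' Builds minimal-variant networks in the middle of the explored connectivity
#' range (p_r = p_f = 8\% by default), lets each settle for a warm-up period,
#' pools instantaneous membrane potentials of sequence neurons over a
#' recording window, fits a Gaussian per seed, and averages the fitted
#' parameters.
#'
#' @param seeds Integer seeds (one network + run each).
#' @param p_r,p_f Sequence connectivities during the baseline run.
#' @param warmup_ms,record_ms Settling and sampling windows.
#' @return A list: \code{mean_mV}, \code{sd_mV} (averages over seeds),
#'   \code{per_seed} data frame, \code{n_samples}.
#' @export
fitBaselineDistribution <- function(seeds = 1:3, p_r = 0.08, p_f = 0.08,
                                    warmup_ms = 1000, record_ms = 1000) {
  cfg <- networkConfig("minimal")
  per <- do.call(rbind, lapply(seeds, function(s) {
    cn <- buildConnectome(cfg, p_r, p_f, seed = s)
    ai <- runAIState(cn, seed = s, warmup_ms = warmup_ms,
                     record_ms = record_ms)
    fit <- fitMembraneGaussian(ai$v)
    data.frame(seed = s, mean_mV = fit$mean, sd_mV = fit$sd,
               rate = ai$rate, n = length(ai$v))
  }))
  list(mean_mV = mean(per$mean_mV), sd_mV = mean(per$sd_mV),
       per_seed = per, n_samples = sum(per$n))
}

#' Empirical normalized width of the membrane-potential distribution
#'
#' In the leak-free, fixed-in-degree minimal model with membrane potentials
#' drawn from a clipped Gaussian whose upper edge sits at the firing
#' threshold, the smallest feedforward probability that still replays at
#' p_r = 0 estimates the normalized distribution width u directly.
#'
#' @param base_seed Master seed.
#' @param pf_values Feedforward probabilities scanned.
#' @param mu,sigma Parameters of the clipped Gaussian draw (mV).
#' @param n_networks,n_trials Replications per point.
#' @return A list: \code{scan} and \code{min_pf_pct} (smallest successful
#'   p_f, percent).
#' @export
scanLeakFreeWidth <- function(base_seed = 1L,
                              pf_values = seq(0.08, 0.16, by = 0.01),
                              mu = -51, sigma = 0.5,
                              n_networks = 3L, n_trials = 3L) {
  cfg <- networkConfig("minimal", leak_free = TRUE,
                       connectivity_mode = "fixed_in_degree")
  scan <- scanGrid(cfg, pr_values = 0, pf_values = pf_values,
                   n_networks = n_networks, n_trials = n_trials,
                   base_seed = base_seed,
                   init = function(cn, seed)
                     initMembraneGaussian(cn, mu, sigma, seed))
  ok <- scan$success_fraction >= 0.8
  list(scan = scan,
       min_pf_pct = if (any(ok)) 100 * min(scan$p_f[ok]) else NA_real_)
}
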