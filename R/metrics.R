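# Gaussian smoothing of a count series (zero-padded convolution).
.gauss_smooth <- function(counts, sd_bins) {
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq.int(-half, half), sd = sd_bins)
  k <- k / sum(k)
  out <- stats::convolve(c(rep(0, half), counts, rep(0, half)), rev(k),
                         type = "open")
  out[(2L * half + 1L):(2L * half + length(counts))]
}

# detection parameters: slow mode for long latencies / leak-free runs
.detect_params <- function(config, kernel_sd = NULL, threshold = NULL) {
  slow <- config$tau_l >= 2 || isTRUE(config$leak_free)
  list(kernel_sd = kernel_sd %||% (if (slow) 7 else 2),
       threshold = threshold %||% (if (slow) 15 else 30),
       slow = slow)
}

#' Smoothed per-assembly population rates of a spike record
#'
#' Bins each assembly's excitatory spikes on the trial window and convolves
#' with a normalized Gaussian kernel. Rates are in spikes/s per neuron. A
#' background series (non-assembly excitatory cells) is included when such
#' cells exist.
#'
#' @param record A \code{"spike_record"}.
#' @param kernel_sd Kernel SD in ms (default 2; 7 in slow mode, i.e. when
#'   \code{tau_l >= 2} ms or the run is leak-free).
#' @param bin_ms Bin width (default 0.5 ms).
#' @return An object of class \code{"rate_series"}: \code{time_ms} (bin
#'   centers), \code{rate} (bins x assemblies matrix), \code{bg_rate} (or
#'   \code{NULL}), and metadata.
#' @export
assemblyRates <- function(record, kernel_sd = NULL, bin_ms = 0.5) {
  stopifnot(inherits(record, "spike_record"))
  kernel_sd <- kernel_sd %||% .detect_params(record$config)$kernel_sd
  t0 <- record$stim_time_ms - 5 * kernel_sd  # pad so the stimulus peak is interior
  t1 <- record$stim_time_ms + record$horizon_ms
  breaks <- seq(t0, t1 + bin_ms, by = bin_ms)
  mids <- breaks[-1L] - bin_ms / 2
  nb <- length(mids)
  q <- record$q
  ev <- record$events
  rate <- matrix(0, nb, q)
  sd_bins <- kernel_sd / bin_ms
  to_rate <- function(counts, n_cells)
    .gauss_smooth(counts, sd_bins) / n_cells / (bin_ms / 1000)
  for (i in seq_len(q)) {
    sel <- record$assembly[ev$neuron] == i & !record$is_inh[ev$neuron]
    cnt <- if (any(sel))
      tabulate(findInterval(ev$time_ms[sel], breaks,
                            rightmost.closed = TRUE), nbins = nb)
    else numeric(nb)
    rate[, i] <- to_rate(cnt, record$M)
  }
  bg_ids <- which(record$assembly == 0L & !record$is_inh)
  bg_rate <- NULL
  if (length(bg_ids)) {
    sel <- ev$neuron %in% bg_ids
    cnt <- if (any(sel))
      tabulate(findInterval(ev$time_ms[sel], breaks,
                            rightmost.closed = TRUE), nbins = nb)
    else numeric(nb)
    bg_rate <- to_rate(cnt, length(bg_ids))
  }
  structure(list(time_ms = mids, rate = rate, bg_rate = bg_rate,
                 kernel_sd = kernel_sd, bin_ms = bin_ms, M = record$M,
                 q = q, stim_time_ms = t0),
            class = "rate_series")
}

# local maxima with minimum height and prominence; returns indices
.find_peaks <- function(y, min_height, min_prominence) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(y[-c(1L, n)] >= y[-c(n - 1L, n)] &
                y[-c(1L, n)] > y[-c(1L, 2L)]) + 1L
  cand <- cand[y[cand] >= min_height]
  keep <- vapply(cand, function(p) {
    h <- y[p]
    l <- p; lm <- h
    while (l > 1L && y[l] <= h) { lm <- min(lm, y[l]); l <- l - 1L }
    if (y[l] <= h) lm <- min(lm, y[l])
    r <- p; rm <- h
    while (r < n && y[r] <= h) { rm <- min(rm, y[r]); r <- r + 1L }
    if (y[r] <= h) rm <- min(rm, y[r])
    (h - max(lm, rm)) >= min_prominence
  }, logical(1))
  cand[keep]
}

# Gaussian fit (amplitude, center, sd) of a rate profile around a peak;
# falls back to rate-weighted moments inside the window
.fit_pulse <- function(time_ms, rate, peak_idx, kernel_sd) {
  half <- 7.5 * kernel_sd
  win <- which(time_ms >= time_ms[peak_idx] - half &
               time_ms <= time_ms[peak_idx] + half)
  df <- data.frame(x = time_ms[win], y = rate[win])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - m)^2 / (2 * s^2)), data = df,
                      start = list(A = rate[peak_idx], m = time_ms[peak_idx],
                                   s = kernel_sd),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    if (is.finite(co["s"]) && abs(co["s"]) > 0)
      return(list(center = unname(co["m"]), sd = abs(unname(co["s"]))))
  }
  w <- pmax(df$y, 0)
  if (sum(w) == 0) return(list(center = time_ms[peak_idx], sd = NA_real_))
  m <- sum(df$x * w) / sum(w)
  list(center = m, sd = sqrt(sum((df$x - m)^2 * w) / sum(w)))
}

#' Detect and classify a replay attempt
#'
#' Applies the three requirement sets for a successful retrieval: (1) every
#' assembly shows a smoothed-rate peak above the detection threshold, the
#' peaks occur in sequence order with inter-peak delays of at least the
#' synaptic latency; (2) a Gaussian fitted to each assembly's rate profile
#' defines a window of three fitted SDs around its center in which the
#' assembly's spike count must lie within 90--110\% of its neuron count (all
#' neurons fire approximately once, no bursting); (3) where background
#' neurons exist, their smoothed rate stays below the threshold throughout.
#' Failures are classified as \code{died_out}, \code{order_violation},
#' \code{burst_or_explosion} or \code{background_active}.
#'
#' @param record A \code{"spike_record"} from one stimulated trial.
#' @param rates Optional precomputed \code{"rate_series"}.
#' @param kernel_sd,threshold Detection overrides; defaults are 2 ms / 30
#'   spikes/s, switching to 7 ms / 15 spikes/s in slow mode (\code{tau_l >= 2}
#'   ms or leak-free).
#' @return An object of class \code{"replay_outcome"}: \code{success},
#'   \code{failure_class}, per-assembly \code{peak_times} (ms),
#'   \code{fitted_sd} (ms), spike \code{counts}, and on success the
#'   asymptotic \code{fwhm_ms} (mean over the last three assemblies) and
#'   \code{speed} (assemblies/ms, mean inverse peak interval over the last
#'   four intervals).
#' @export
detectReplay <- function(record, rates = NULL, kernel_sd = NULL, threshold = NULL) {
  stopifnot(inherits(record, "spike_record"))
  pars <- .detect_params(record$config, kernel_sd, threshold)
  if (is.null(rates)) rates <- assemblyRates(record, kernel_sd = pars$kernel_sd)
  q <- record$q
  thr <- pars$threshold
  peak_times <- fitted_sd <- centers <- rep(NA_real_, q)
  counts <- rep(NA_integer_, q)
  ev <- record$events
  for (i in seq_len(q)) {
    y <- rates$rate[, i]
    pk <- .find_peaks(y, thr, thr / 2)
    if (!length(pk)) next
    p <- pk[1L]  # earliest qualifying peak after stimulation
    peak_times[i] <- rates$time_ms[p]
    fit <- .fit_pulse(rates$time_ms, y, p, pars$kernel_sd)
    centers[i] <- fit$center
    fitted_sd[i] <- fit$sd
    if (is.finite(fit$sd)) {
      sel <- record$assembly[ev$neuron] == i & !record$is_inh[ev$neuron] &
        ev$time_ms >= fit$center - 3 * fit$sd &
        ev$time_ms <= fit$center + 3 * fit$sd
      counts[i] <- sum(sel)
    }
  }
  # total spikes per assembly in the trial window (diagnostic only; the
  # burst criterion counts within +/- 3 fitted SDs of each peak)
  tot <- vapply(seq_len(q), function(i)
    sum(record$assembly[ev$neuron] == i & !record$is_inh[ev$neuron]),
    numeric(1))
  M <- record$M
  # sustained above-threshold activity at the end of the horizon marks
  # runaway (bursting/exploding) dynamics rather than a single pulse
  late <- rates$time_ms > max(rates$time_ms) - 50
  runaway <- any(rates$rate[late, ] > thr)
  failure <- "none"
  if (runaway || any(!is.na(counts) & counts > 1.1 * M)) {
    failure <- "burst_or_explosion"
  } else if (anyNA(peak_times) || any(!is.na(counts) & counts < 0.9 * M) ||
             anyNA(counts)) {
    failure <- "died_out"
  } else if (any(diff(peak_times) <= 0) ||
             any(diff(peak_times) < record$config$tau_l - 1e-9)) {
    failure <- "order_violation"
  } else if (!is.null(rates$bg_rate) && any(rates$bg_rate >= thr)) {
    failure <- "background_active"
  }
  out <- list(success = failure == "none", failure_class = failure,
              peak_times = peak_times, fitted_sd = fitted_sd,
              centers = centers, counts = counts, total_counts = tot,
              threshold = thr, kernel_sd = pars$kernel_sd, q = q,
              fwhm_ms = NA_real_, speed = NA_real_)
  if (out$success) {
    out$fwhm_ms <- mean(2 * sqrt(2 * log(2)) * utils::tail(fitted_sd, 3L))
    # fitted pulse centers give sub-bin timing; fall back to raw peak bins
    ctr <- ifelse(is.finite(centers), centers, peak_times)
    iv <- utils::tail(diff(ctr), 4L)
    if (any(iv <= 0)) iv <- utils::tail(diff(peak_times), 4L)
    out$speed <- mean(1 / iv)
  }
  structure(out, class = "replay_outcome")
}

#' @export
print.replay_outcome <- function(x, ...) {
  if (x$success)
    cat(sprintf("<replay_outcome> success; speed %.3f assemblies/ms, FWHM %.2f ms\n",
                x$speed, x$fwhm_ms))
  else
    cat(sprintf("<replay_outcome> failure (%s)\n", x$failure_class))
  invisible(x)
}

#' Asymptotic pulse width and speed of a successful replay
#'
#' @param outcome A successful \code{"replay_outcome"}.
#' @return Named vector: \code{fwhm_ms} (2 sqrt(2 ln 2) times the fitted SD,
#'   averaged over the last three assemblies) and \code{speed}
#'   (assemblies/ms).
#' @export
measurePulse <- function(outcome) {
  stopifnot(inherits(outcome, "replay_outcome"))
  if (!outcome$success) stop("pulse metrics are only defined for successful replays")
  c(fwhm_ms = outcome$fwhm_ms, speed = outcome$speed)
}

# order-independent per-point seed derivation
.point_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) + 7919 * i) %% 2147483647)
}

#' Scan a connectivity grid for replay success, speed and width
#'
#' For every (p_r, p_f) point, builds \code{n_networks} independent
#' connectomes and runs \code{n_trials} stimulated trials on each (separated
#' by quiet intervals), classifies each trial with
#' \code{\link{detectReplay}}, and aggregates: the success fraction over all
#' trials, and — at points where at least 80\% of trials succeed — the mean
#' asymptotic speed and FWHM over the successful trials. All randomness
#' derives from \code{base_seed}; per-point seeds are order-independent, so
#' splitting the grid across workers cannot change the result.
#'
#' @param config A \code{"network_config"}.
#' @param pr_values,pf_values Connection probabilities; the scan covers their
#'   full cross product unless \code{pairs} is given.
#' @param pairs Optional data frame with columns \code{p_r}, \code{p_f}
#'   listing exact points (e.g. a diagonal neighborhood).
#' @param n_networks,n_trials Networks per point and trials per network.
#' @param base_seed Integer master seed.
#' @param warmup_ms,horizon_ms,inter_trial_ms Trial protocol (see
#'   \code{\link{runReplayTrial}}).
#' @param init Optional \code{function(connectome, seed)} returning a
#'   \code{"sim_state"}; when given, every trial is run independently from a
#'   fresh initial state with no warm-up (manual membrane-initialization
#'   protocol).
#' @param min_success Success-fraction threshold for reporting metrics
#'   (default 0.8).
#' @return A data frame of class \code{"grid_scan"}: \code{p_r}, \code{p_f},
#'   \code{success_fraction}, \code{speed}, \code{fwhm_ms},
#'   \code{failure_class} (dominant among failed trials, or "none").
#' @export
scanGrid <- function(config, pr_values, pf_values, pairs = NULL,
                     n_networks = 5L, n_trials = 5L, base_seed = 1L,
                     warmup_ms = 1000, horizon_ms = 300,
                     inter_trial_ms = 1000, init = NULL, min_success = 0.8) {
  stopifnot(inherits(config, "network_config"))
  if (is.null(pairs))
    pairs <- expand.grid(p_r = pr_values, p_f = pf_values,
                         KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(pairs))
  for (ptx in seq_len(nrow(pairs))) {
    p_r <- pairs$p_r[ptx]; p_f <- pairs$p_f[ptx]
    pseed <- .point_seed(base_seed, ptx)
    outcomes <- list()
    for (j in seq_len(n_networks)) {
      nseed <- as.integer((as.numeric(pseed) + 131 * j) %% 2147483000)
      cn <- buildConnectome(config, p_r, p_f, seed = nseed)
      if (is.null(init)) {
        recs <- runReplayTrial(cn, seed = nseed + 1L, n_trials = n_trials,
                               warmup_ms = warmup_ms, horizon_ms = horizon_ms,
                               inter_trial_ms = inter_trial_ms)
        if (n_trials == 1L) recs <- list(recs)
      } else {
        recs <- lapply(seq_len(n_trials), function(k) {
          st <- init(cn, nseed + 1000L * k)
          runReplayTrial(cn, seed = nseed + 1000L * k + 1L, state = st,
                         warmup_ms = 0, horizon_ms = horizon_ms,
                         n_trials = 1L)
        })
      }
      outcomes <- c(outcomes, lapply(recs, detectReplay))
    }
    succ <- vapply(outcomes, function(o) o$success, logical(1))
    frac <- mean(succ)
    speed <- fwhm <- NA_real_
    if (frac >= min_success && any(succ)) {
      speed <- mean(vapply(outcomes[succ], function(o) o$speed, numeric(1)))
      fwhm <- mean(vapply(outcomes[succ], function(o) o$fwhm_ms, numeric(1)))
    }
    fcl <- vapply(outcomes, function(o) o$failure_class, character(1))
    fcl <- fcl[fcl != "none"]
    res[[ptx]] <- data.frame(
      p_r = p_r, p_f = p_f, success_fraction = frac,
      speed = speed, fwhm_ms = fwhm,
      failure_class = if (length(fcl)) names(sort(table(fcl),
                                                  decreasing = TRUE))[1L]
                      else "none")
  }
  out <- do.call(rbind, res)
  attr(out, "n_networks") <- n_networks
  attr(out, "n_trials") <- n_trials
  attr(out, "base_seed") <- base_seed
  class(out) <- c("grid_scan", "data.frame")
  out
}
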