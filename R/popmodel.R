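#' Membrane-potential distribution shapes for the population model
#'
#' The time-discrete population model describes each assembly by a
#' static-shaped probability density of membrane potentials with finite width
#' \code{U} (in potential units), whose right edge sits at position \code{x}
#' relative to the firing threshold at 0. Two shapes are supported: a
#' rectangle (uniform density on \code{[-U, 0]}) and a clipped Gaussian with
#' standard deviation \code{U/4}, truncated at two standard deviations around
#' its mean and renormalized.
#'
#' @param kind One of \code{"rectangle"} or \code{"clipped_gaussian"}.
#' @param U Distribution width (potential units), must be > 0.
#' @return An object of class \code{"replay_shape"}.
#' @examples
#' sh <- distributionShape("rectangle", U = 1)
#' areaAboveThreshold(sh, 0.5)
#' @export
distributionShape <- function(kind = c("rectangle", "clipped_gaussian"), U = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(U) || length(U) != 1L || !is.finite(U) || U <= 0)
    stop("'U' must be a single positive number")
  structure(list(kind = kind, U = U, sigma = U / 4), class = "replay_shape")
}

#' @export
print.replay_shape <- function(x, ...) {
  cat(sprintf("<replay_shape> %s, U = %g\n", x$kind, x$U))
  invisible(x)
}

# mass of the clipped standard Gaussian inside +/- 2 sd
.cgauss_mass <- stats::pnorm(2) - stats::pnorm(-2)

#' Fraction of a membrane-potential distribution above the firing threshold
#'
#' Given a distribution shape and the position \code{x} of its right edge
#' (threshold at 0, support \code{[x - U, x]}), returns the probability mass
#' above threshold. It is 0 for \code{x <= 0}, 1 for \code{x >= U}, and
#' non-decreasing in \code{x}.
#'
#' @param shape A \code{"replay_shape"} object.
#' @param x Right-edge position(s); vectorized.
#' @return Fraction(s) in \code{[0, 1]}.
#' @export
areaAboveThreshold <- function(shape, x) {
  if (!inherits(shape, "replay_shape")) stop("invalid shape: not a 'replay_shape'")
  U <- shape$U
  if (shape$kind == "rectangle") {
    pmin(pmax(x, 0), U) / U
  } else if (shape$kind == "clipped_gaussian") {
    s <- shape$sigma
    m <- x - 2 * s  # distribution mean when the right edge is at x
    a <- (stats::pnorm(2) - stats::pnorm(-m / s)) / .cgauss_mass
    a[x <= 0] <- 0
    a[x >= U] <- 1
    pmin(pmax(a, 0), 1)
  } else {
    stop("invalid shape kind: ", shape$kind)
  }
}

#' Parameters of the time-discrete population model
#'
#' Holds the recurrent weight \code{R}, feedforward weight \code{F}, the
#' distribution shape, the common initial right-edge position \code{x0 <= 0},
#' the external input amplitude \code{J} applied to assembly 1 at t = 1, the
#' sequence length \code{q} and the step budget \code{t_max}. An input
#' \code{J > U - x0} is clamped to \code{U - x0} with a warning (a larger J
#' always fully activates the first assembly).
#'
#' @param R Recurrent weight, >= 0 (potential units).
#' @param F Feedforward weight, >= 0.
#' @param U Distribution width, > 0; ignored when \code{shape} is an object.
#' @param shape Shape kind string or a \code{"replay_shape"} object.
#' @param x0 Initial right-edge position, <= 0.
#' @param J External input to assembly 1 at t = 1, in \code{[0, U - x0]}.
#' @param q Sequence length, >= 1.
#' @param t_max Maximum number of time steps (default \code{50 * q}).
#' @return An object of class \code{"population_params"}.
#' @export
populationParams <- function(R, F, U = 1, shape = "rectangle", x0 = 0,
                             J = U - x0, q = 10, t_max = 50 * q) {
  if (!inherits(shape, "replay_shape")) shape <- distributionShape(shape, U)
  U <- shape$U
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R), R >= 0,
            is.numeric(F), length(F) == 1L, is.finite(F), F >= 0,
            is.numeric(x0), length(x0) == 1L, is.finite(x0),
            is.numeric(J), length(J) == 1L, is.finite(J), J >= 0,
            q >= 1, t_max >= 1)
  if (x0 > 0) stop("'x0' must be <= 0")
  if (J > U - x0) {
    warning(sprintf("J = %g exceeds U - x0 = %g; clamped", J, U - x0))
    J <- U - x0
  }
  structure(list(R = R, F = F, shape = shape, U = U, x0 = x0, J = J,
                 q = as.integer(q), t_max = as.integer(t_max)),
            class = "population_params")
}

# tolerance absorbing floating-point accumulation in the full-activation test
.full_eps <- 1e-12
# progress cutoff: when every edge advances by less than this (relative to U)
# in a step, the run can never reach full activation and is declared a failure
.stall_eps <- 1e-9

.new_trajectory <- function(params) {
  q <- params$q
  x <- matrix(params$x0, nrow = params$t_max + 1L, ncol = q)
  a <- matrix(0, nrow = params$t_max + 1L, ncol = q)
  structure(list(x = x, a = a, t_bar = rep(NA_integer_, q),
                 filled = 0L, success = FALSE, S = NA_real_, params = params),
            class = "population_trajectory")
}

#' Advance the population model by one time step
#'
#' Applies the update \code{x_t = x_{t-1} + R a_{t-1}(i) + F a_{t-1}(i-1) +
#' J_t(i)} with \code{a_t(0) = 0} by convention, then computes the new
#' activity as the increment in threshold-crossed mass. Row \code{t} of the
#' trajectory must not yet be filled.
#'
#' @param traj A \code{"population_trajectory"} (from \code{runPopulationReplay}
#'   with \code{steps = 0}, or a previous call).
#' @param t Time step index, >= 1.
#' @param Jt Per-assembly external input at time t (scalar or length-q vector).
#' @return The updated trajectory.
#' @export
stepPopulation <- function(traj, t, Jt = 0) {
  p <- traj$params
  if (t != traj$filled + 1L) stop("trajectory filled through t = ", traj$filled,
                                  "; next step must be t = ", traj$filled + 1L)
  if (t > p$t_max) stop("t exceeds t_max")
  Jt <- rep_len(Jt, p$q)
  if (any(Jt < 0)) stop("negative external input")
  r <- t + 1L  # row for time t (row 1 is t = 0)
  a_prev <- traj$a[r - 1L, ]
  a_ff <- c(0, a_prev[-p$q])  # a_{t-1}^{(i-1)}, with a^{(0)} == 0
  x_new <- traj$x[r - 1L, ] + p$R * a_prev + p$F * a_ff + Jt
  A_new <- areaAboveThreshold(p$shape, x_new)
  A_old <- areaAboveThreshold(p$shape, traj$x[r - 1L, ])
  traj$x[r, ] <- x_new
  traj$a[r, ] <- A_new - A_old
  newly_full <- which(is.na(traj$t_bar) & x_new >= p$U - .full_eps)
  traj$t_bar[newly_full] <- t
  traj$filled <- t
  traj
}

#' Run a replay trial of the population model
#'
#' Iterates the population model from the common initial condition
#' \code{x_0 = x0}, applying the external input \code{J} to assembly 1 at
#' t = 1, until the last assembly fully crosses the threshold or \code{t_max}
#' is reached. Success means the last assembly's distribution fully crossed
#' (right edge at least \code{U}) at some finite step; exceeding \code{t_max}
#' is a failure, not an error.
#'
#' @param params A \code{"population_params"} object.
#' @param steps Optional number of steps to run (default: until success or
#'   \code{t_max}). \code{steps = 0} returns the initialized trajectory for
#'   manual stepping.
#' @return A \code{"population_trajectory"} with fields \code{x}, \code{a}
#'   (rows t = 0..T, columns assemblies), \code{t_bar} (first full-activation
#'   step per assembly, NA if never), \code{success}, and average speed
#'   \code{S = q / t_bar[q]} on success.
#' @examples
#' p <- populationParams(R = 0, F = 1, U = 1, J = 1, q = 10)
#' tr <- runPopulationReplay(p)
#' tr$success; tr$S
#' @export
runPopulationReplay <- function(params, steps = NULL) {
  stopifnot(inherits(params, "population_params"))
  traj <- .new_trajectory(params)
  if (!is.null(steps) && steps == 0) return(traj)
  q <- params$q
  J1 <- c(params$J, rep(0, q - 1L))
  limit <- if (is.null(steps)) params$t_max else min(steps, params$t_max)
  for (t in seq_len(limit)) {
    traj <- stepPopulation(traj, t, if (t == 1L) J1 else 0)
    if (!is.na(traj$t_bar[q])) break
    # no meaningful progress is possible anymore at double precision: the
    # edges are stalling short of the threshold (e.g. exactly on the
    # R + F = U - x0 boundary, where full activation takes infinitely long)
    if (t > 1L && max(traj$x[t + 1L, ] - traj$x[t, ]) < .stall_eps * params$U)
      break
  }
  T_f <- traj$filled
  traj$x <- traj$x[seq_len(T_f + 1L), , drop = FALSE]
  traj$a <- traj$a[seq_len(T_f + 1L), , drop = FALSE]
  traj$success <- !is.na(traj$t_bar[q])
  traj$S <- if (traj$success) q / traj$t_bar[q] else NA_real_
  traj
}

#' @export
print.population_trajectory <- function(x, ...) {
  p <- x$params
  cat(sprintf("<population_trajectory> %s, q = %d, R = %g, F = %g, U = %g, x0 = %g, J = %g\n",
              p$shape$kind, p$q, p$R, p$F, p$U, p$x0, p$J))
  cat(sprintf("  steps run: %d; success: %s", x$filled, x$success))
  if (x$success) cat(sprintf("; t_bar(q) = %d; S = %.4g", x$t_bar[p$q], x$S))
  cat("\n")
  invisible(x)
}

#' Pulse width (FWHM, in time steps) of one assembly's activity series
#'
#' The full width at half maximum is taken as \code{2*sqrt(2*log(2))} times
#' the standard deviation of the time-step index weighted by the activity, as
#' for a Gaussian pulse. Requires a fully activated assembly (activities sum
#' to 1).
#'
#' @param a Activity series of one assembly, indexed by time step
#'   (t = 0, 1, ...; any leading offset cancels in the variance).
#' @return FWHM in time steps.
#' @export
pulseFWHM <- function(a) {
  if (abs(sum(a) - 1) > 1e-9)
    stop("undefined width: activities must sum to 1 (fully activated assembly)")
  k <- seq_along(a) - 1
  mu <- sum(k * a)
  2 * sqrt(2 * log(2)) * sqrt(sum((k - mu)^2 * a))
}

#' Average pulse speed of a population-model trajectory
#'
#' @param traj A completed \code{"population_trajectory"}.
#' @return \code{S = q / t_bar[q]} in assemblies per time step on success,
#'   otherwise \code{NA}.
#' @export
pulseSpeed <- function(traj) {
  stopifnot(inherits(traj, "population_trajectory"))
  if (isTRUE(traj$success)) traj$params$q / traj$t_bar[traj$params$q] else NA_real_
}

#' Asymptotic pulse width of a trajectory
#'
#' Mean FWHM over the last three assemblies (only defined when all of them
#' fully activated).
#'
#' @param traj A completed \code{"population_trajectory"}.
#' @return Mean FWHM in time steps, or \code{NA} if the last three assemblies
#'   did not all fully activate.
#' @export
trajectoryFWHM <- function(traj) {
  stopifnot(inherits(traj, "population_trajectory"))
  q <- traj$params$q
  idx <- seq.int(max(1L, q - 2L), q)
  if (anyNA(traj$t_bar[idx])) return(NA_real_)
  mean(vapply(idx, function(i) pulseFWHM(traj$a[, i]), numeric(1)))
}

#' Long-format data frame of a population trajectory
#'
#' @param x A \code{"population_trajectory"}.
#' @param ... Unused.
#' @return A data frame with columns \code{t}, \code{assembly}, \code{x},
#'   \code{a}.
#' @export
as.data.frame.population_trajectory <- function(x, ...) {
  Tn <- nrow(x$x)
  q <- x$params$q
  data.frame(t = rep(seq_len(Tn) - 1L, times = q),
             assembly = rep(seq_len(q), each = Tn),
             x = as.vector(x$x), a = as.vector(x$a))
}

#' JSON-ready summary of a population trajectory
#'
#' @param traj A completed \code{"population_trajectory"}.
#' @return A list with \code{success}, \code{t_bar}, \code{S}, \code{fwhm}.
#' @export
trajectorySummary <- function(traj) {
  list(success = traj$success,
       t_bar = as.integer(traj$t_bar),
       S = traj$S,
       fwhm = trajectoryFWHM(traj))
}

#' Export a population trajectory to CSV (long format) and JSON summary
#'
#' @param traj A completed \code{"population_trajectory"}.
#' @param csv Path of the CSV file (t, assembly, x, a), or \code{NULL} to skip.
#' @param json Path of the JSON summary, or \code{NULL} to skip.
#' @return Invisibly, the summary list.
#' @export
exportTrajectory <- function(traj, csv = NULL, json = NULL) {
  if (!is.null(csv))
    utils::write.csv(as.data.frame(traj), csv, row.names = FALSE)
  s <- trajectorySummary(traj)
  if (!is.null(json))
    jsonlite::write_json(s, json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(s)
}
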