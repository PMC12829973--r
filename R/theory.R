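#' Necessary total-connectivity condition for sequence replay
#'
#' Replay of any assembly that receives no external input requires the summed
#' recurrent and feedforward weights to exceed the distance the distribution
#' must travel: \code{R + F > U - x0}. Necessary for any distribution shape;
#' the boundary itself is not sufficient (full activation then takes
#' infinitely many steps).
#'
#' @param R,F Recurrent and feedforward weights (>= 0, potential units).
#' @param U Distribution width (> 0).
#' @param x0 Initial right-edge position (<= 0).
#' @return Logical.
#' @export
conditionTotalConnectivity <- function(R, F, U, x0 = 0) {
  R + F > U - x0
}

#' Necessary minimum-feedforward condition for sequence replay
#'
#' An assembly whose distribution starts a gap \code{-x0} below threshold can
#' only generate activity if the total feedforward input exceeds that gap:
#' \code{F > -x0}.
#'
#' @param F Feedforward weight (>= 0).
#' @param x0 Initial right-edge position (<= 0).
#' @return Logical.
#' @export
conditionMinFeedforward <- function(F, x0 = 0) {
  F > -x0
}

# log of the partial sums sum_{k=i}^{t} C(k-1, i-1) * rho^(k-i) for
# t = i .. t_max, computed stably in log space (no overflow for t ~ 1e4).
.log_binom_cumsum <- function(i, t_max, rho) {
  k <- i:t_max
  if (rho == 0) {
    # only the k = i term survives (0^0 = 1)
    lt <- c(0, rep(-Inf, length(k) - 1L))
  } else {
    lt <- lchoose(k - 1, i - 1) + (k - i) * log(rho)
  }
  M <- max(lt)
  log(cumsum(exp(lt - M))) + M
}

#' Linear estimate of the rectangle-model distribution edge
#'
#' Closed-form solution of the linearized rectangle model with \code{x0 = 0}:
#' \code{x_hat = J (F/U)^(i-1) sum_{k=i}^{t} C(k-1, i-1) (R/U)^(k-i)} for
#' \code{t >= i}, and 0 for \code{t < i}. It equals the exact simulation for
#' every assembly up to (and including) the first one to fully activate, and
#' upper-bounds it everywhere. Evaluated in log space, stable up to
#' \code{t = 1e4} and beyond.
#'
#' @param i Assembly index (>= 1).
#' @param t Time step(s); vectorized.
#' @param J Initial external input to assembly 1.
#' @param R,F Recurrent and feedforward weights.
#' @param U Distribution width.
#' @return Estimated edge position(s) \code{x_hat} (same length as \code{t}).
#' @examples
#' linearEstimate(i = 4, t = 9, J = 1, R = 0, F = 0.5, U = 1)  # 0.125
#' @export
linearEstimate <- function(i, t, J, R, F, U = 1) {
  stopifnot(i >= 1, U > 0, J >= 0, R >= 0, F >= 0)
  i <- as.integer(i)
  out <- numeric(length(t))
  live <- t >= i
  if (!any(live) || J == 0) return(out)
  if (F == 0 && i > 1) return(out)
  lpref <- log(J) + (i - 1) * log(F / U)
  lcs <- .log_binom_cumsum(i, max(t[live]), R / U)
  out[live] <- exp(lpref + lcs[t[live] - i + 1L])
  out
}

#' First fully activated assembly under the linear estimate
#'
#' Scans (t, then i) for the smallest pair with \code{x_hat_t^(i) >= U}; the
#' linear estimate is exact up to that point, so the returned index \code{m}
#' and step \code{t_bar_m} are those of the true rectangle model.
#'
#' @param J,R,F,U Model parameters as in \code{\link{linearEstimate}}.
#' @param i_max Largest assembly index scanned.
#' @param t_max Largest time step scanned.
#' @return A list with \code{m} and \code{t_bar_m} (both \code{NA} if no
#'   assembly fully activates within the bounds).
#' @export
firstFullActivation <- function(J, R, F, U = 1, i_max = 10L, t_max = 1000L) {
  stopifnot(U > 0)
  best <- list(m = NA_integer_, t_bar_m = NA_integer_)
  for (i in seq_len(i_max)) {
    xh <- linearEstimate(i, i:t_max, J, R, F, U)
    hit <- which(xh >= U - 1e-12)
    if (length(hit)) {
      t_i <- i + hit[1L] - 1L
      if (is.na(best$t_bar_m) || t_i < best$t_bar_m)
        best <- list(m = i, t_bar_m = t_i)
    }
    if (!is.na(best$t_bar_m) && i >= best$t_bar_m) break  # t >= i: no later i can win
  }
  best
}

#' Finite-length speed condition for replay
#'
#' Tests whether a sequence of \code{q} assemblies can be replayed at average
#' speed \code{S} (assemblies per time step) under the linear estimate:
#' the last assembly must reach \code{U} by step \code{floor(q/S)}. The
#' left-hand side grows as \code{S} decreases, so feasibility is monotone in
#' speed.
#'
#' @param S Target speed in (0, 1].
#' @param R,F Recurrent and feedforward weights.
#' @param U Distribution width.
#' @param J Initial input (default \code{U}).
#' @param q Sequence length.
#' @return Logical.
#' @export
speedConditionFiniteQ <- function(S, R, F, U = 1, J = U, q = 10L) {
  stopifnot(S > 0, S <= 1)
  t <- floor(q / S)
  linearEstimate(q, t, J, R, F, U) >= U - 1e-12
}

#' Replay speed estimate from the linear rectangle model
#'
#' Finds the smallest step \code{t* >= q} at which the linear estimate of the
#' last assembly reaches \code{U} and returns \code{S_hat = q / t*}; the
#' largest speed at which the finite-length condition holds.
#'
#' @param R,F Recurrent and feedforward weights.
#' @param U Distribution width.
#' @param J Initial input (default \code{U}).
#' @param q Sequence length.
#' @param t_max Largest step scanned (default 1e4, covering speeds down to
#'   about 1e-3 for q = 10).
#' @return Speed in (0, 1], or \code{NA} if no \code{t <= t_max} qualifies.
#' @export
estimateSpeed <- function(R, F, U = 1, J = U, q = 10L, t_max = 1e4L) {
  stopifnot(U > 0)
  xh <- linearEstimate(q, q:t_max, J, R, F, U)
  hit <- which(xh >= U - 1e-12)
  if (!length(hit)) return(NA_real_)
  q / (q + hit[1L] - 1L)
}

#' Asymptotic speed condition (infinitely long sequences)
#'
#' Closed-form limit of the finite-length condition as the sequence length
#' grows, independent of the initial input: replay at speed \code{S} requires
#' \deqn{F/U \ge 1 - R/U \quad (R/U \le 1-S), \qquad
#'       F/U \ge S ((1-S)/(R/U))^{1/S - 1} \quad (R/U > 1-S).}
#' \code{S = 0} is accepted as a sentinel for the slow-propagation limit,
#' where the condition reduces to \code{R + F >= U}.
#'
#' @param S Speed in (0, 1], or 0 for the limit.
#' @param R,F Recurrent and feedforward weights.
#' @param U Distribution width.
#' @return Logical.
#' @export
asymptoticSpeedCondition <- function(S, R, F, U = 1) {
  F / U >= minFeedforwardForSpeed(R, U = U, S = S) / U - 1e-12
}

#' Minimal feedforward weight sustaining a given asymptotic speed
#'
#' Direct evaluation of the asymptotic speed condition solved for \code{F}:
#' continuous, non-increasing in \code{R} and non-decreasing in \code{S}.
#' \code{S = 0} gives the slow-propagation limit \code{max(U - R, 0)}.
#'
#' @param R Recurrent weight(s); vectorized.
#' @param U Distribution width.
#' @param S Speed in [0, 1].
#' @return Minimal \code{F} (same length as \code{R}).
#' @export
minFeedforwardForSpeed <- function(R, U = 1, S) {
  stopifnot(S >= 0, S <= 1, U > 0)
  rho <- R / U
  if (S == 0) return(U * pmax(1 - rho, 0))
  low <- rho <= 1 - S
  f <- numeric(length(rho))
  f[low] <- 1 - rho[low]
  f[!low] <- S * ((1 - S) / rho[!low])^(1 / S - 1)
  U * f
}

#' Minimal feedforward weight at finite sequence length
#'
#' Bisection on \code{F} for the smallest value satisfying the finite-length
#' speed condition at given \code{R}, \code{S} and \code{q}. As \code{q}
#' grows this border converges to \code{\link{minFeedforwardForSpeed}}.
#'
#' @param R Recurrent weight.
#' @param S Speed in (0, 1].
#' @param q Sequence length.
#' @param U Distribution width.
#' @param J Initial input (default \code{U}).
#' @param tol Bisection tolerance on \code{F/U}.
#' @return Minimal \code{F}, or \code{NA} if even \code{F = 2U(1 + R/U)} fails.
#' @export
minFeedforwardFiniteQ <- function(R, S, q = 10L, U = 1, J = U, tol = 1e-10) {
  hi <- 2 * (U + R)
  if (!speedConditionFiniteQ(S, R, hi, U, J, q)) return(NA_real_)
  lo <- 0
  while (hi - lo > tol * U) {
    mid <- (lo + hi) / 2
    if (speedConditionFiniteQ(S, R, mid, U, J, q)) hi <- mid else lo <- mid
  }
  hi
}
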