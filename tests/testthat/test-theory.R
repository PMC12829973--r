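test_that("necessary replay conditions evaluate strictly", {
  expect_false(conditionTotalConnectivity(0.5, 0.4, U = 1, x0 = 0))
  expect_true(conditionTotalConnectivity(0.5, 0.6, U = 1, x0 = 0))
  expect_false(conditionTotalConnectivity(0, 0.5, U = 1, x0 = -0.5))  # boundary
  expect_true(conditionMinFeedforward(0.1, x0 = 0))
  expect_false(conditionMinFeedforward(0.5, x0 = -0.5))  # boundary not strict
  expect_true(conditionMinFeedforward(0.6, x0 = -0.5))
})

test_that("closed-form edge estimate matches the naive binomial sum", {
  expect_equal(linearEstimate(4, 9, J = 1, R = 0, F = 0.5), 0.125)
  expect_equal(linearEstimate(2, 3, J = 1, R = 0.5, F = 0.5), 1)  # J(F/U)(1+2R/U)
  expect_equal(linearEstimate(3, 2, J = 1, R = 0.7, F = 0.9), 0)  # t < i
  set.seed(3)
  for (rep in 1:20) {
    i <- sample(1:6, 1); t <- sample(i:(i + 12), 1)
    J <- stats::runif(1, 0.1, 1); R <- stats::runif(1, 0, 1.2)
    F <- stats::runif(1, 0.05, 1.2); U <- stats::runif(1, 0.5, 2)
    expect_equal(linearEstimate(i, t, J, R, F, U),
                 naive_linear_estimate(i, t, J, R, F, U), tolerance = 1e-10)
  }
  # log-space evaluation stays finite and monotone out to t = 1e4
  xh <- linearEstimate(10, 10:10000, J = 1, R = 0.97, F = 0.05)
  expect_true(all(is.finite(xh)))
  expect_true(all(diff(xh) >= 0))
})

test_that("edge estimate solves its defining difference equation", {
  set.seed(9)
  for (rep in 1:20) {
    i <- sample(2:6, 1); t <- sample((i + 1):(i + 10), 1)
    J <- stats::runif(1, 0.1, 1); R <- stats::runif(1, 0, 1.2)
    F <- stats::runif(1, 0.05, 1.2); U <- stats::runif(1, 0.5, 2)
    le <- function(ii, tt) linearEstimate(ii, tt, J, R, F, U)
    rhs <- le(i, t - 1) + R * (le(i, t - 1) - le(i, t - 2)) / U +
      F * (le(i - 1, t - 1) - le(i - 1, t - 2)) / U
    expect_equal(le(i, t), rhs, tolerance = 1e-9)
  }
})

test_that("estimate is exact up to first full activation and bounds the model above", {
  set.seed(21)
  for (rep in 1:12) {
    J <- stats::runif(1, 0.2, 0.9)
    R <- stats::runif(1, 0.2, 1.2)
    F <- stats::runif(1, 0.3, 1.2)
    p <- populationParams(R = R, F = F, U = 1, J = J, q = 6, t_max = 150)
    tr <- runPopulationReplay(p)
    act <- firstFullActivation(J, R, F, U = 1, i_max = 6, t_max = 150)
    Tn <- nrow(tr$x) - 1L
    for (i in seq_len(p$q)) {
      xh <- linearEstimate(i, 0:Tn, J, R, F, 1)
      expect_true(all(xh >= tr$x[, i] - 1e-9))
      if (!is.na(act$m) && i <= act$m) {
        tt <- 0:min(Tn, act$t_bar_m)
        expect_equal(xh[tt + 1L], tr$x[tt + 1L, i], tolerance = 1e-9)
      }
    }
    # first full activation index/time agree with the exact simulation
    if (!is.na(act$m) && act$t_bar_m <= Tn) {
      sim_first <- which.min(tr$t_bar)
      expect_equal(min(tr$t_bar, na.rm = TRUE), act$t_bar_m)
    }
  }
})

test_that("first full activation scans find the known special cases", {
  expect_equal(firstFullActivation(J = 1, R = 0.3, F = 0.5, U = 1),
               list(m = 1L, t_bar_m = 1L))
  a <- firstFullActivation(J = 0.5, R = 0.6, F = 0.2, U = 1, t_max = 500)
  expect_equal(a$m, 1L)         # J + R > U activates assembly 1 eventually
  expect_false(is.na(a$t_bar_m))
  a2 <- firstFullActivation(J = 0.5, R = 0.5, F = 0, U = 1, t_max = 2000)
  expect_true(is.na(a2$m))      # J + R = U: never within finite time
})

test_that("speed condition is monotone in the target speed", {
  expect_true(speedConditionFiniteQ(1, R = 0, F = 1, U = 1, J = 1, q = 10))
  for (S in c(1, 0.5, 0.2, 0.05))
    expect_false(speedConditionFiniteQ(S, R = 0, F = 0.5, U = 1, J = 1, q = 10))
  # R = 0.6, F = 0.5: fails at S = 1 but succeeds at some slower speed
  expect_false(speedConditionFiniteQ(1, R = 0.6, F = 0.5, U = 1, J = 1, q = 10))
  S_hat <- estimateSpeed(R = 0.6, F = 0.5, U = 1, J = 1, q = 10)
  expect_true(S_hat < 1 && S_hat > 0)
  set.seed(5)
  for (rep in 1:10) {
    R <- stats::runif(1, 0, 1); F <- stats::runif(1, 0.1, 1.2)
    Ss <- sort(stats::runif(5, 0.05, 1))
    ok <- vapply(Ss, function(S) speedConditionFiniteQ(S, R = R, F = F,
                                                       U = 1, J = 1, q = 10),
                 logical(1))
    # once true at a speed, true at every slower speed
    expect_true(all(diff(ok) <= 0))
  }
})

test_that("speed estimates agree with a brute-force threshold scan", {
  expect_equal(estimateSpeed(R = 0, F = 2, U = 1, J = 1, q = 10), 1)
  expect_equal(estimateSpeed(R = 0, F = 1, U = 1, J = 1, q = 10), 1)
  expect_true(is.na(estimateSpeed(R = 0, F = 0.5, U = 1, J = 1, q = 10)))
  for (pars in list(c(0.9, 0.2), c(0.5, 0.6), c(0.8, 0.3))) {
    R <- pars[1]; F <- pars[2]
    ts <- 10:2000
    xh <- vapply(ts, function(t) naive_linear_estimate(10, t, 1, R, F, 1),
                 numeric(1))
    t_star <- ts[which(xh >= 1)[1]]
    expect_equal(estimateSpeed(R = R, F = F, U = 1, J = 1, q = 10), 10 / t_star)
  }
})

test_that("asymptotic speed condition reduces to its closed-form limits", {
  # S = 1 requires F >= U regardless of R
  for (R in c(0, 0.3, 1.5)) {
    expect_true(asymptoticSpeedCondition(1, R, F = 1, U = 1))
    expect_false(asymptoticSpeedCondition(1, R, F = 0.99, U = 1))
  }
  # S -> 0 sentinel reduces to R + F >= U
  expect_true(asymptoticSpeedCondition(0, R = 0.4, F = 0.6, U = 1))
  expect_false(asymptoticSpeedCondition(0, R = 0.4, F = 0.55, U = 1))
  expect_true(asymptoticSpeedCondition(0, R = 1.2, F = 0, U = 1))
  # branch selection: R/U = 0.5 < 1 - S at S = 0.25 gives F/U >= 0.5
  expect_equal(minFeedforwardForSpeed(0.5, U = 1, S = 0.25), 0.5)
})

test_that("minimal feedforward border is continuous, monotone, and q-convergent", {
  Rg <- seq(0, 1.5, by = 0.01)
  for (S in c(0.2, 0.5, 0.9)) {
    f <- minFeedforwardForSpeed(Rg, U = 1, S = S)
    expect_true(all(diff(f) <= 1e-9))          # non-increasing in R
    expect_lt(max(abs(diff(f))), 0.05)         # no jumps across the branch point
  }
  R0 <- 0.4
  f_by_S <- vapply(c(0.1, 0.3, 0.6, 0.9), function(S)
    minFeedforwardForSpeed(R0, U = 1, S = S), numeric(1))
  expect_true(all(diff(f_by_S) >= 0))          # non-decreasing in S
  # finite-length borders approach the closed form as sequences grow
  for (S in c(0.25, 0.5)) {
    f_inf <- minFeedforwardForSpeed(R0, U = 1, S = S)
    errs <- vapply(c(10L, 50L, 200L), function(q)
      abs(minFeedforwardFiniteQ(R0, S, q = q) - f_inf), numeric(1))
    expect_true(all(diff(errs) < 0))
    expect_lt(errs[3], 0.03)
  }
})
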