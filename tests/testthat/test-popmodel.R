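test_that("threshold-crossed mass behaves correctly for both shapes", {
  for (kind in c("rectangle", "clipped_gaussian")) {
    sh <- distributionShape(kind, U = 1)
    expect_equal(areaAboveThreshold(sh, 0), 0)
    expect_equal(areaAboveThreshold(sh, -0.3), 0)
    expect_equal(areaAboveThreshold(sh, 1), 1)
    expect_equal(areaAboveThreshold(sh, 2), 1)
    expect_equal(areaAboveThreshold(sh, 0.5), 0.5)  # symmetry about midpoint
    xs <- seq(-0.5, 1.5, by = 0.01)
    a <- areaAboveThreshold(sh, xs)
    expect_true(all(diff(a) >= 0))
    expect_true(all(a >= 0 & a <= 1))
  }
  # clipped-Gaussian mass agrees with numerical integration of its density
  sh <- distributionShape("clipped_gaussian", U = 2)
  s <- sh$sigma
  dens <- function(v, m) ifelse(abs(v - m) <= 2 * s,
                                stats::dnorm(v, m, s) /
                                  (stats::pnorm(2) - stats::pnorm(-2)), 0)
  for (x in c(0.2, 0.7, 1.1, 1.9)) {
    num <- stats::integrate(dens, 0, x, m = x - 2 * s)$value
    expect_equal(areaAboveThreshold(sh, x), num, tolerance = 1e-7)
  }
  expect_error(areaAboveThreshold(list(kind = "rectangle"), 0.5), "replay_shape")
})

test_that("single-step updates follow the edge-position recursion", {
  p <- populationParams(R = 0, F = 0, U = 1, J = 0.5, q = 2)
  tr <- runPopulationReplay(p, steps = 0)
  tr <- stepPopulation(tr, 1, c(0.5, 0))
  expect_equal(tr$x[2, 1], 0.5)   # x_1^(1) = J
  expect_equal(tr$a[2, 1], 0.5)   # a_1^(1) = J/U
  expect_equal(tr$x[2, 2], 0)
  expect_error(stepPopulation(tr, 3, 0), "next step")
  expect_error(stepPopulation(tr, 2, -0.1), "negative")

  # J = U fully activates the first assembly at t = 1
  tr1 <- runPopulationReplay(populationParams(R = 0, F = 1, U = 1, J = 1, q = 3))
  expect_equal(tr1$t_bar[1], 1L)
})

test_that("replay trials reproduce the exact special-case solutions", {
  # F = U, R = 0: one assembly per step, S = 1
  tr <- runPopulationReplay(populationParams(R = 0, F = 1, U = 1, J = 1, q = 10))
  expect_true(tr$success)
  expect_equal(tr$t_bar[10], 10L)
  expect_equal(tr$S, 1)
  expect_equal(pulseSpeed(tr), 1)

  # F < U without recurrence: geometric attenuation x_i^(i) = J (F/U)^(i-1)
  tr2 <- runPopulationReplay(populationParams(R = 0, F = 0.5, U = 1, J = 1, q = 10))
  expect_false(tr2$success)
  expect_true(is.na(pulseSpeed(tr2)))
  for (i in 1:6) expect_equal(tr2$x[i + 1L, i], 0.5^(i - 1))

  # exact connectivity boundary R + F = U - x0 never retrieves (both shapes)
  for (kind in c("rectangle", "clipped_gaussian")) {
    for (J in c(0.6, 1)) {
      trb <- runPopulationReplay(populationParams(R = 0.5, F = 0.5, U = 1,
                                                  shape = kind, J = J, q = 2))
      expect_false(trb$success)
    }
  }
})

test_that("pulse width is the activity-weighted FWHM", {
  expect_equal(pulseFWHM(c(0, 1, 0)), 0)
  expect_equal(pulseFWHM(c(0.5, 0.5)), 2 * sqrt(2 * log(2)) * 0.5)
  expect_equal(pulseFWHM(c(0.25, 0.5, 0.25)), 2 * sqrt(2 * log(2)) * sqrt(0.5))
  expect_error(pulseFWHM(c(0.2, 0.3)), "sum to 1")
})

test_that("trajectory invariants hold over randomized parameters", {
  set.seed(42)
  for (rep in 1:30) {
    kind <- sample(c("rectangle", "clipped_gaussian"), 1)
    U <- stats::runif(1, 0.5, 2)
    x0 <- -stats::runif(1, 0, 0.5)
    p <- populationParams(R = stats::runif(1, 0, 1.5), F = stats::runif(1, 0, 1.5),
                          U = U, shape = kind, x0 = x0,
                          J = stats::runif(1, 0.1, U - x0), q = 6, t_max = 200)
    tr <- runPopulationReplay(p)
    # monotone edges (no hyperpolarizing mechanism)
    expect_true(all(apply(tr$x, 2, function(v) all(diff(v) >= -1e-12))))
    # bounded cumulative activity; exactly 1 when fully activated
    cum <- apply(tr$a, 2, cumsum)
    expect_true(all(tr$a >= -1e-12))
    expect_true(all(cum <= 1 + 1e-9))
    for (i in seq_len(p$q)) {
      if (!is.na(tr$t_bar[i]))
        expect_equal(cum[nrow(cum), i], 1, tolerance = 1e-9)
    }
    # causality: input only reaches assembly i at step i
    for (i in 2:p$q)
      if (nrow(tr$a) > i)
        expect_true(all(tr$a[seq_len(i), i] == 0))
  }
})

test_that("total connectivity at or below U - x0 never retrieves (any shape)", {
  set.seed(7)
  for (rep in 1:25) {
    kind <- sample(c("rectangle", "clipped_gaussian"), 1)
    U <- stats::runif(1, 0.5, 2)
    x0 <- -stats::runif(1, 0, 0.5)
    tot <- stats::runif(1, 0.1, 1) * (U - x0)  # R + F <= U - x0
    R <- stats::runif(1, 0, 1) * tot
    p <- populationParams(R = R, F = tot - R, U = U, shape = kind, x0 = x0,
                          J = U - x0, q = sample(2:8, 1), t_max = 300)
    expect_false(runPopulationReplay(p)$success)
  }
})

test_that("strong feedforward gives one-step propagation downstream", {
  set.seed(11)
  for (rep in 1:15) {
    kind <- sample(c("rectangle", "clipped_gaussian"), 1)
    U <- stats::runif(1, 0.5, 2)
    x0 <- -stats::runif(1, 0, 0.4)
    p <- populationParams(R = stats::runif(1, 0, 1), F = (U - x0) * stats::runif(1, 1, 1.5),
                          U = U, shape = kind, x0 = x0, J = U - x0, q = 8)
    tr <- runPopulationReplay(p)
    expect_true(tr$success)
    tb <- tr$t_bar
    expect_false(anyNA(tb))
    expect_true(all(diff(tb) == 1L))
  }
})

test_that("rectangle and clipped-Gaussian success regions agree except at low F", {
  grid <- expand.grid(R = seq(0, 1.5, by = 0.25), F = seq(0, 1.5, by = 0.25))
  succ <- sapply(c("rectangle", "clipped_gaussian"), function(kind)
    apply(grid, 1, function(g) {
      runPopulationReplay(populationParams(R = g["R"], F = g["F"], U = 1,
                                           shape = kind, J = 1, q = 10))$success
    }))
  hiF <- grid$F >= 0.5
  expect_identical(succ[hiF, 1], succ[hiF, 2])
  # overall disagreement confined to a minor fraction of the grid
  expect_lt(mean(succ[, 1] != succ[, 2]), 0.15)
})

test_that("trajectories export to long CSV and JSON summaries", {
  tr <- runPopulationReplay(populationParams(R = 0.4, F = 0.8, U = 1, J = 1, q = 5))
  df <- as.data.frame(tr)
  expect_named(df, c("t", "assembly", "x", "a"))
  expect_equal(nrow(df), nrow(tr$x) * 5)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  s <- exportTrajectory(tr, csv, js)
  expect_true(file.exists(csv) && file.exists(js))
  rt <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(rt$success, tr$success)
  expect_equal(rt$S, tr$S, tolerance = 1e-12)
})
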