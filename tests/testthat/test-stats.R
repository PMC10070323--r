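test_that("reblock recovers the i.i.d. standard error", {
  errs <- sapply(1:3, function(sd_) {
    set.seed(sd_)
    n <- 2^14
    rb <- reblock(rnorm(n))
    rb$stderr / (1 / sqrt(n))
  })
  expect_lt(abs(mean(errs) - 1), 0.15)
})

test_that("reblock recovers the AR(1) autocorrelation inflation", {
  phi <- 0.9
  n <- 2^15
  ratios <- sapply(1:3, function(sd_) {
    set.seed(100 + sd_)
    x <- as.numeric(arima.sim(list(ar = phi), n))
    rb <- reblock(x)
    truth <- sd(x) * sqrt((1 + phi) / (1 - phi)) / sqrt(n)
    rb$stderr / truth
  })
  expect_lt(abs(mean(ratios) - 1), 0.20)
})

test_that("reblock handles degenerate and short input", {
  rb <- reblock(rep(3.25, 64))
  expect_equal(rb$mean, 3.25)
  expect_equal(rb$stderr, 0)
  expect_error(reblock(1:5), "length >= 8")
})

test_that("reblock mean is the exact arithmetic mean at every level", {
  set.seed(2)
  x <- rnorm(1000, mean = -2.9, sd = 0.01)
  expect_identical(reblock(x)$mean, mean(x))
})

test_that("noiseless linear trajectories recover the slope exactly", {
  w_star <- 0.5; b_star <- 0
  k <- seq(10, 200, by = 10)
  gap <- exp(-k / 80) + 0.002              # E_VMC - E_DMC along training
  E_ex <- -1.0
  # construction satisfying E_DMC - E_ex = w * gap + b
  E_DMC <- E_ex + w_star * gap + b_star
  E_VMC <- E_DMC + gap
  traj <- energy_trajectory(k, E_VMC, E_DMC)
  fit <- suppressWarnings(fit_linear_relation(traj))  # perfect fit by design
  expect_equal(fit$w, w_star, tolerance = 1e-12)
  expect_error(fit_linear_relation(traj[1:2, ]), "at least 3")
  flat <- energy_trajectory(1:5, rep(1.5, 5) + 0.5, rep(1, 5))
  expect_error(fit_linear_relation(flat), "degenerate")
})

test_that("noisy slope estimates are statistically consistent", {
  set.seed(11)
  w_star <- 0.8
  k <- seq_len(20) * 10
  gap <- seq(2e-3, 4e-2, length.out = 20)
  cover <- replicate(100, {
    E_DMC <- -1 + w_star * gap + rnorm(20, sd = 1e-4)
    traj <- energy_trajectory(k, E_DMC + gap, E_DMC)
    fit <- fit_linear_relation(traj)
    abs(fit$w - w_star) < 3 * fit$w_stderr
  })
  expect_gt(mean(cover), 0.9)
})

test_that("the relative-energy extrapolation formula is exact arithmetic", {
  expect_equal(extrapolate_relative(2e-3, 3e-3, 0), 2e-3)
  expect_equal(extrapolate_relative(2e-3, 3e-3, -1), 3e-3)
  expect_equal(extrapolate_relative(2e-3, 3e-3, 0.5), 1.5e-3)
  # fixed point: equal VMC and DMC differences are returned unchanged
  for (w in c(-2, -0.5, 0, 0.7, 3))
    expect_equal(extrapolate_relative(1.2e-3, 1.2e-3, w), 1.2e-3)
})

test_that("per-step extrapolated differences are constant for exact linearity", {
  w_star <- 0.6; b_star <- 1e-3
  k <- seq(20, 200, by = 20)
  gapA <- exp(-k / 60) * 5e-2
  gapB <- exp(-k / 90) * 8e-2
  EA <- -10 + w_star * gapA + b_star
  EB <- -12.5 + w_star * gapB + b_star       # true asymptote difference -2.5
  trajA <- energy_trajectory(k, EA + gapA, EA)
  trajB <- energy_trajectory(k, EB + gapB, EB)
  ed <- suppressWarnings(extrapolation_distribution(trajA, trajB))
  expect_equal(ed$values$dE_ex, rep(-2.5, length(k)), tolerance = 1e-10)
  expect_error(extrapolation_distribution(trajA, trajB[-1, ]),
               "common step grid")
})

test_that("extrapolation reduces the spread of noisy relative energies", {
  set.seed(21)
  w_star <- 0.7
  k <- seq(10, 200, by = 10)
  gapA <- exp(-k / 60) * 5e-2
  gapB <- exp(-k / 90) * 8e-2
  res <- replicate(100, {
    EA <- -10 + w_star * gapA + rnorm(length(k), sd = 2e-4)
    EB <- -12.5 + w_star * gapB + rnorm(length(k), sd = 2e-4)
    ed <- extrapolation_distribution(
      energy_trajectory(k, EA + gapA, EA),
      energy_trajectory(k, EB + gapB, EB))
    c(ex = ed$sd, raw = ed$sd_raw_dmc)
  })
  expect_gt(mean(res["ex", ] < res["raw", ]), 0.9)
})
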