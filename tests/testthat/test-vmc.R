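test_that("Metropolis chains reproduce a known 1-D target density", {
  sys <- harmonic1d_system()
  tr <- make_trial("gauss_harmonic", sys)     # psi = exp(-x^2/2), psi^2 ~ N(0, 1/2)
  ms <- metropolis_sample(tr, sys,
                          vmc_params(n_walkers = 500, n_steps = 2000,
                                     step_size = 1.0, seed = 1),
                          record = "ensembles", thin = 10)
  draws <- unlist(ms$ensembles[-(1:20)])      # drop early ensembles
  expect_gt(length(draws), 5e4)
  ks <- suppressWarnings(ks.test(draws, "pnorm", sd = sqrt(0.5)))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("hydrogenic sampling reproduces the analytic <r> of the 1s density", {
  h <- builtin_system("H")
  tr <- make_trial("hydrogenic", h)
  ms <- metropolis_sample(tr, h,
                          vmc_params(n_walkers = 400, n_steps = 1500,
                                     step_size = 0.6, seed = 2),
                          record = "ensembles", thin = 10)
  keep <- do.call(rbind, ms$ensembles[-(1:15)])
  r <- sqrt(rowSums(keep^2))
  se <- sd(r) / sqrt(length(r) / 10)          # conservative correlation factor
  expect_lt(abs(mean(r) - 1.5), 3 * se)
})

test_that("acceptance rate decreases monotonically with step size", {
  he <- builtin_system("He")
  tr <- make_trial("he_pade", he, list(b = 0.35))
  acc <- sapply(c(0.1, 0.5, 2.0), function(ss) {
    mean(sapply(1:3, function(sd_)
      metropolis_sample(tr, he, vmc_params(n_walkers = 100, n_steps = 150,
                                           step_size = ss, seed = sd_))$acceptance))
  })
  expect_true(all(diff(acc) < 0))
})

test_that("vmc_energy is exact with zero variance for eigenstate trials", {
  h <- builtin_system("H")
  est <- vmc_energy(make_trial("hydrogenic", h),
                    params = vmc_params(n_walkers = 200, n_steps = 200, seed = 1))
  expect_equal(est$mean, -0.5, tolerance = 1e-12)
  expect_lt(est$stderr, 1e-10)
  w3 <- builtin_system("harmonic3d")
  est <- vmc_energy(make_trial("gauss_harmonic", w3),
                    params = vmc_params(n_walkers = 200, n_steps = 200, seed = 1))
  expect_equal(est$mean, 1.5, tolerance = 1e-12)
})

test_that("he_pade variational energy matches the quadrature oracle", {
  he <- builtin_system("He")
  b <- 0.35
  est <- vmc_energy(make_trial("he_pade", he, list(b = b)),
                    params = vmc_params(n_walkers = 800, n_steps = 1200,
                                        step_size = 0.5, seed = 4))
  oracle <- he_pade_quadrature_energy(b)
  expect_lt(abs(est$mean - oracle), 3 * est$stderr)
  # and the variational bound against the exact helium energy
  expect_gt(est$mean, E_EXACT_HE - 3 * est$stderr)
})

test_that("optimizing the hydrogenic exponent recovers Z = 1", {
  h <- builtin_system("H")
  tr <- make_trial("hydrogenic", h, list(Z = 0.8))
  opt <- optimize_trial(tr, h, params = vmc_params(n_walkers = 300, n_steps = 10,
                                                   step_size = 0.8, seed = 3),
                        n_iters = 250, learning_rate = 0.05)
  expect_false(opt$diverged)
  expect_equal(unname(opt$trial$params["Z"]), 1, tolerance = 0.02)
})

test_that("the variational energy does not increase under optimization", {
  he <- builtin_system("He")
  finals <- sapply(1:3, function(sd_) {
    tr <- make_trial("he_pade", he, list(b = 2.0))
    opt <- optimize_trial(tr, he,
                          params = vmc_params(n_walkers = 250, n_steps = 10,
                                              step_size = 0.5, seed = sd_),
                          n_iters = 200, learning_rate = 0.1)
    c(first = mean(head(opt$trajectory$energy, 20)),
      last = mean(tail(opt$trajectory$energy, 20)))
  })
  # seed-averaged: the optimized energy does not exceed the starting one
  expect_lte(mean(finals["last", ]), mean(finals["first", ]))
})

test_that("zero learning rate leaves parameters and trajectory unchanged", {
  he <- builtin_system("He")
  tr <- make_trial("he_pade", he, list(b = 0.5))
  opt <- optimize_trial(tr, he, params = vmc_params(n_walkers = 100, n_steps = 5,
                                                    seed = 6),
                        n_iters = 20, learning_rate = 0)
  expect_identical(as.numeric(opt$trial$params), as.numeric(tr$params))
})
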