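test_that("exact eigenstate trials have constant local energy", {
  h <- builtin_system("H")
  t1 <- make_trial("hydrogenic", h, list(Z = 1))
  set.seed(1)
  X <- fndmc:::random_configs(h, 200)
  el <- local_energy(t1, X = X)
  expect_equal(el, rep(-0.5, 200), tolerance = 1e-12)
  w3 <- builtin_system("harmonic3d")
  tg <- make_trial("gauss_harmonic", w3)
  el <- local_energy(tg, X = fndmc:::random_configs(w3, 200))
  expect_equal(el, rep(1.5, 200), tolerance = 1e-12)
  expect_lt(sd(local_energy(t1, X = fndmc:::random_configs(h, 1000))), 1e-8)
})

test_that("two-fermion 1-D exact trial has local energy 2 omega", {
  sys <- builtin_system("harmonic1d2f", list(omega = 1))
  tf <- make_trial("harmonic1d2f", sys)
  el <- local_energy(tf, X = fndmc:::random_configs(sys, 100))
  expect_equal(el, rep(2, 100), tolerance = 1e-10)
  expect_equal(tf$exact_energy, 2)
})

test_that("he_pade local energy matches a finite-difference Laplacian oracle", {
  he <- builtin_system("He")
  tr <- make_trial("he_pade", he, list(b = 0.5))
  x <- c(0.5, 0, 0, -0.5, 0, 0)
  el <- local_energy(tr, X = x)
  # central-difference Laplacian of psi at h = 1e-4, fully independent path
  h <- 1e-4
  psi <- function(v) {
    r1 <- sqrt(sum(v[1:3]^2)); r2 <- sqrt(sum(v[4:6]^2))
    u <- sqrt(sum((v[1:3] - v[4:6])^2))
    exp(-2 * (r1 + r2) + u / (2 * (1 + 0.5 * u)))
  }
  lap <- 0
  for (k in 1:6) {
    vp <- x; vm <- x
    vp[k] <- vp[k] + h; vm[k] <- vm[k] - h
    lap <- lap + (psi(vp) + psi(vm) - 2 * psi(x)) / h^2
  }
  v_pot <- -2 / 0.5 - 2 / 0.5 + 1 / 1
  el_fd <- -0.5 * lap / psi(x) + v_pot
  expect_equal(el, el_fd, tolerance = 1e-5)
})

test_that("derivative consistency holds at 100 random configurations", {
  he <- builtin_system("He")
  be <- builtin_system("Be")
  trials <- list(
    make_trial("he_pade", he, list(b = 0.35)),
    make_trial("slater_jastrow", be),
    make_trial("neural", be, list(n_det = 2, width = 8, init_seed = 3))
  )
  for (tr in trials) {
    chk <- check_derivatives(tr, n_configs = 100, seed = 42)
    expect_lt(chk$max_rel_grad, 1e-5)
    expect_lt(chk$max_rel_lap, 1e-3)
  }
})

test_that("determinant-bearing trials are antisymmetric in same-spin pairs", {
  be <- builtin_system("Be")
  for (tr in list(make_trial("slater_jastrow", be),
                  make_trial("neural", be, list(n_det = 2, width = 8)))) {
    expect_lt(check_antisymmetry(tr, n_configs = 25, seed = 7), 1e-11)
  }
})

test_that("he_pade is nodeless: positive sign on random configurations", {
  he <- builtin_system("He")
  tr <- make_trial("he_pade", he, list(b = 0.5))
  expect_true(tr$nodeless)
  set.seed(5)
  lp <- tr$logpsi(fndmc:::random_configs(he, 1e4, sd = 2))
  expect_true(all(lp$sign == 1))
})

test_that("construction self-check rejects broken derivative contracts", {
  h <- builtin_system("H")
  broken <- make_trial("hydrogenic", h, self_check = FALSE)
  broken$grad <- function(X) 2 * (-1) * fndmc:::as_walker_matrix(X)  # wrong
  expect_error(fndmc:::self_check_trial(broken), "derivatives inconsistent")
  expect_error(make_trial("nonesuch", h), "unknown trial family")
})

test_that("cusp diagnostics recover the Kato values", {
  h <- builtin_system("H")
  cc <- cusp_check(make_trial("hydrogenic", h))
  expect_equal(cc$nuclear$estimate, -1, tolerance = 1e-3)
  expect_false(cc$nuclear$violated)
  he <- builtin_system("He")
  for (b in c(0.2, 0.8)) {
    cc <- cusp_check(make_trial("he_pade", he, list(b = b)))
    expect_equal(cc$nuclear$estimate, -2, tolerance = 1e-3)
    expect_equal(cc$electron_pair$estimate, 0.5, tolerance = 1e-3)
  }
  # a cuspless Gaussian on H must be flagged
  w3 <- builtin_system("harmonic3d")
  tg <- make_trial("gauss_harmonic", w3)
  tg$system <- h   # evaluate the Gaussian around the hydrogen nucleus
  cc <- cusp_check(tg, system = h)
  expect_true(cc$nuclear$violated)
})

test_that("parameter gradients agree with finite differences", {
  he <- builtin_system("He")
  tr <- make_trial("he_pade", he, list(b = 0.4))
  set.seed(9)
  X <- fndmc:::random_configs(he, 20)
  expect_equal(tr$param_grad(X), fndmc:::fd_param_grad(tr, X),
               tolerance = 1e-6, ignore_attr = TRUE)
  be <- builtin_system("Be")
  tn <- make_trial("neural", be, list(n_det = 2, width = 6, init_seed = 2))
  X <- fndmc:::random_configs(be, 5)
  expect_equal(tn$param_grad(X), fndmc:::fd_param_grad(tn, X),
               tolerance = 1e-5, ignore_attr = TRUE)
})
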