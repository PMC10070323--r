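test_that("distance to a hyperplane node is the exact point-plane distance", {
  sys <- free_system(d = 3)
  nrm <- c(1, 2, 2)
  tr <- make_trial("linear_node", sys, list(normal = nrm, offset = 0.5))
  for (p in list(c(0.8, 0.3, -0.4), c(-0.2, 0.9, 0.1), c(1.1, -0.7, 0.6))) {
    dn <- distance_to_node(tr, p, tol = 1e-7)
    expect_equal(dn$distance, abs(sum(nrm * p) - 0.5) / sqrt(sum(nrm^2)),
                 tolerance = 1e-5)
    expect_lt(abs(sum(nrm * dn$witness) - 0.5), 1e-4)  # witness on the node
  }
})

test_that("two-fermion node distance matches the analytic plane distance", {
  sys <- builtin_system("harmonic1d2f")
  tr <- make_trial("harmonic1d2f", sys)
  dn <- distance_to_node(tr, c(0.3, -0.1), tol = 1e-6)
  expect_equal(dn$distance, 0.4 / sqrt(2), tolerance = 1e-4)
  # near-node point
  expect_lt(distance_to_node(tr, c(0.2, 0.2 + 1e-9), tol = 1e-6)$distance,
            1e-6)
  # nodeless trials have no surface to measure
  he <- builtin_system("He")
  expect_error(distance_to_node(make_trial("he_pade", he), c(1, 0, 0, -1, 0, 0)),
               "nodeless")
})

test_that("distance_to_node upper-bounds a dense grid search", {
  sys <- builtin_system("harmonic1d2f")
  tr <- make_trial("harmonic1d2f", sys, list(alpha = 0.3))
  gx <- seq(-3, 3, length.out = 601)
  grid <- as.matrix(expand.grid(gx, gx))
  sgn <- tr$logpsi(grid)$sign
  sgn_m <- matrix(sgn, 601, 601)
  # cells adjacent to a sign change approximate the node
  flip <- which(sgn_m[-601, ] * sgn_m[-1, ] < 0, arr.ind = TRUE)
  node_pts <- cbind((gx[flip[, 1]] + gx[flip[, 1] + 1]) / 2, gx[flip[, 2]])
  set.seed(4)
  for (rep in 1:10) {
    p <- runif(2, -1, 1)
    if (abs(p[1] - p[2]) < 0.05) next
    d_pkg <- distance_to_node(tr, p, tol = 1e-6)$distance
    d_grid <- min(sqrt((node_pts[, 1] - p[1])^2 + (node_pts[, 2] - p[2])^2))
    expect_gt(d_pkg, d_grid - 2e-2)     # never closer than the brute force
    expect_lt(d_pkg, d_grid + 2e-2)     # and an accurate upper bound here
  }
})

test_that("projected node samples lie on the node with the target density", {
  sys <- builtin_system("harmonic1d2f")
  tr <- make_trial("harmonic1d2f", sys)
  sp <- sample_node_points(tr, params = nodal_params(K = 3000, epsilon = 0.15,
                                                     projection_tol = 1e-4,
                                                     seed = 2))
  expect_true(all(abs(sp$points[, 1] - sp$points[, 2]) < 1e-3))
  # the on-node marginal of psi^2 restricted to the shell is Gaussian in
  # mu = (x1 + x2)/sqrt(2) with variance 1/2
  mu <- (sp$points[, 1] + sp$points[, 2]) / sqrt(2)
  ks <- suppressWarnings(ks.test(mu[seq(1, 3000, by = 3)], "pnorm",
                                 sd = sqrt(0.5)))
  expect_lt(unname(ks$statistic), 0.05)
  he <- builtin_system("He")
  expect_error(sample_node_points(make_trial("he_pade", he)), "nodeless")
})

test_that("the divergence is zero on itself and exact for parallel planes", {
  sys <- free_system(d = 2)
  base <- make_trial("linear_node", sys, list(normal = c(1, 0), offset = 0))
  ptol <- 1e-4
  nd <- nodal_divergence(base, base,
                         nodal_params(K = 400, projection_tol = ptol, seed = 5))
  expect_lt(nd$D, 2 * ptol)
  for (delta in c(0.05, 0.1, 0.2)) {
    shifted <- make_trial("linear_node", sys,
                          list(normal = c(1, 0), offset = delta))
    nd <- nodal_divergence(base, shifted,
                           nodal_params(K = 400, projection_tol = ptol,
                                        seed = 6))
    expect_lt(abs(nd$D - delta), 3 * max(nd$stderr, ptol))
  }
})

test_that("the divergence grows monotonically as the node rotates away", {
  sys <- builtin_system("harmonic1d2f")
  exact <- make_trial("harmonic1d2f", sys)
  Ds <- sapply(c(0.1, 0.25, 0.4), function(alpha) {
    rot <- make_trial("harmonic1d2f", sys, list(alpha = alpha))
    nodal_divergence(exact, rot, nodal_params(K = 600, seed = 8))$D
  })
  expect_true(all(Ds >= 0))
  expect_true(all(diff(Ds) > 0))
})

test_that("divergence agrees with a dense-grid oracle on offset nodes", {
  sys <- builtin_system("harmonic1d2f")
  t0 <- make_trial("harmonic1d2f", sys)
  dlt <- 0.2 / sqrt(2)                    # node x1 = x2 + 0.2
  t2 <- make_trial("harmonic1d2f", sys, list(delta = dlt))
  nd <- nodal_divergence(t0, t2, nodal_params(K = 1500, seed = 9))
  # parallel lines: every sampled point is exactly dlt away
  expect_lt(abs(nd$D - dlt), 3 * max(nd$stderr, 1e-4))
})

test_that("wavefunction slices expose sign structure over the default square", {
  he <- builtin_system("He")
  tr <- make_trial("he_pade", he)
  base <- init_walkers(he, 1, seed = 1)
  sl <- wavefunction_slice(tr, base, moving_electron = 1, n_grid = 41)
  expect_equal(range(sl$x), c(-5, 5))
  expect_true(all(sl$sign == 1))           # nodeless: uniform sign mask
  # a determinant trial shows a sign boundary when a same-spin electron moves
  be <- builtin_system("Be")
  t2 <- make_trial("slater_jastrow", be)
  base2 <- init_walkers(be, 1, seed = 2)
  sl2 <- wavefunction_slice(t2, base2, moving_electron = 1, extent = 3,
                            n_grid = 61)
  expect_true(any(sl2$sign > 0) && any(sl2$sign < 0))
})

test_that("the beryllium spherical cut covers the stated grid", {
  be <- builtin_system("Be")
  tr <- make_trial("slater_jastrow", be)
  cut <- be_nodal_cut(tr, n_grid = 15)
  expect_equal(range(cut$r1), c(0.1, 2.1))
  expect_equal(range(cut$costheta1), c(-1, 1))
  expect_equal(range(cut$r3), c(0.1, 2.1))
  expect_true(all(is.finite(cut$field)))
  h <- builtin_system("H")
  expect_error(be_nodal_cut(make_trial("hydrogenic", h)), "4-electron")
})
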