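test_that("XYZ files round-trip through Angstrom within 1e-6", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen molecule",
               "H 0.0 0.0 0.0",
               "H 0.0 0.0 0.7414"), f)
  sys <- load_xyz(f)
  expect_equal(length(sys$nuclear_charges), 2)
  expect_equal(sys$nuclear_charges, c(1, 1))
  expect_equal(sys$n_up, 1)
  expect_equal(sys$n_down, 1)
  expect_equal(sys$nuclear_positions[2, 3], 0.7414 * 1.8897259886,
               tolerance = 1e-9)
  f2 <- tempfile(fileext = ".xyz")
  write_xyz(sys, f2)
  sys2 <- load_xyz(f2)
  expect_equal(sys2$nuclear_positions, sys$nuclear_positions,
               tolerance = 1e-6)
})

test_that("XYZ parse errors name the offending line", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("3", "count disagrees with rows",
               "H 0 0 0", "H 0 0 1"), f)
  expect_error(load_xyz(f), "declares 3 atoms but 2")
  writeLines(c("1", "bad symbol", "Xx 0 0 0"), f)
  expect_error(load_xyz(f), "unknown element symbol")
  writeLines(c("1", "bad coordinate", "H 0 zero 0"), f)
  expect_error(load_xyz(f), "malformed")
})

test_that("nitrogen bond length in Angstrom converts to 2.1 bohr", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("2", "N2", "N 0 0 0", "N 0 0 1.1112"), f)
  sys <- load_xyz(f)
  d <- sqrt(sum((sys$nuclear_positions[1, ] - sys$nuclear_positions[2, ])^2))
  expect_equal(d, 2.1, tolerance = 1e-3)
})

test_that("builtin catalog covers atoms, N2 and the harmonic fixtures", {
  be <- builtin_system("Be")
  expect_equal(be$nuclear_charges, 4)
  expect_equal(c(be$n_up, be$n_down), c(2L, 2L))
  n2 <- builtin_system("N2", list(bond_length = 2.1))
  expect_equal(n2$nuclear_charges, c(7, 7))
  expect_equal(c(n2$n_up, n2$n_down), c(7L, 7L))
  expect_equal(abs(n2$nuclear_positions[1, 3] - n2$nuclear_positions[2, 3]),
               2.1)
  expect_error(builtin_system("N2", list(bond_length = -1)), "> 0")
  expect_error(builtin_system("unobtainium"), "unknown")
  expect_true(all(c("H", "Ar", "N2", "harmonic1d2f") %in% list_systems()))
})

test_that("walker initialization is seeded, bounded and count-preserving", {
  h <- builtin_system("H")
  expect_identical(init_walkers(h, 100, seed = 1), init_walkers(h, 100, seed = 1))
  be <- builtin_system("Be")
  X <- init_walkers(be, 1000, seed = 7)
  r <- sqrt(X[, 1]^2 + X[, 2]^2 + X[, 3]^2)
  expect_true(all(is.finite(X)))
  expect_lt(mean(r), 10)
  n2 <- builtin_system("N2", list(bond_length = 2.1))
  X2 <- init_walkers(n2, 10, seed = 0)
  expect_equal(dim(X2), c(10L, 14L * 3L))
  expect_error(init_walkers(h, 0), ">= 1")
})

test_that("spin and charge invariants are enforced", {
  expect_error(make_system(matrix(0, 1, 3), 1, 0, 1), "n_up >= n_down")
  expect_error(make_system(matrix(0, 1, 3), -1, 1, 0), "> 0")
  expect_error(make_system(matrix(0, 2, 3), 1, 1, 0), "must agree")
})
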