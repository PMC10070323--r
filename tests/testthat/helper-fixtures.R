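# Shared fixtures and independent oracles used across the test files.

# exact nonrelativistic reference energies (Hartree)
E_EXACT_HE <- -2.903724
E_EXACT_BE <- -14.66736

# a free particle in d dimensions with a flat potential (for hyperplane
# node fixtures; the Gaussian envelope of the trials keeps sampling proper)
free_system <- function(d = 3, n_up = 1, n_down = 0) {
  make_system(NULL, numeric(0), n_up, n_down, d = d, label = "free",
              potential = function(X) numeric(nrow(X)))
}

harmonic1d_system <- function(omega = 1) {
  make_system(NULL, numeric(0), 1, 0, d = 1,
              label = "1-D harmonic well",
              potential = function(X) 0.5 * omega^2 * rowSums(X^2))
}

# --------------------------------------------------------------------------
# Independent quadrature oracle for the helium Pade-Jastrow expectation
# <psi|H|psi>/<psi|psi>.  Works directly in the radial coordinates
# (r1, r2, u) with the interparticle volume element r1 r2 u and the
# analytic log-derivatives of the trial form
#   log psi = -Z (r1 + r2) + u / (2 (1 + b u)),
# so it shares no code with the trial or sampler implementations.
he_pade_quadrature_energy <- function(b, Z = 2, n_r = 48, n_u = 32,
                                      r_max = 9) {
  gl <- function(n, a, bnd) {            # Gauss-Legendre nodes on [a, bnd]
    # Golub-Welsch from the Jacobi matrix of Legendre polynomials
    k <- seq_len(n - 1)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- beta
    J[cbind(k + 1, k)] <- beta
    ev <- eigen(J, symmetric = TRUE)
    x <- ev$values
    w <- 2 * ev$vectors[1, ]^2
    list(x = (bnd - a) / 2 * x + (a + bnd) / 2, w = (bnd - a) / 2 * w)
  }
  qr_ <- gl(n_r, 0, r_max)
  num <- 0; den <- 0
  for (i in seq_len(n_r)) {
    r1 <- qr_$x[i]; w1 <- qr_$w[i]
    r2 <- qr_$x; w2 <- qr_$w
    for (j in seq_len(n_r)) {
      qu <- gl(n_u, abs(r1 - r2[j]), r1 + r2[j])
      u <- qu$x
      fu <- 1 / (2 * (1 + b * u)^2)             # d log psi / d u
      c1 <- (r1^2 + u^2 - r2[j]^2) / (2 * r1 * u)
      c2 <- (r2[j]^2 + u^2 - r1^2) / (2 * r2[j] * u)
      t_loc <- 0.5 * ((Z^2 + fu^2 - 2 * Z * fu * c1) +
                      (Z^2 + fu^2 - 2 * Z * fu * c2))
      v_loc <- -Z / r1 - Z / r2[j] + 1 / u
      rho <- exp(-2 * Z * (r1 + r2[j]) + u / (1 + b * u)) * r1 * r2[j] * u
      num <- num + w1 * w2[j] * sum(qu$w * rho * (t_loc + v_loc))
      den <- den + w1 * w2[j] * sum(qu$w * rho)
    }
  }
  num / den
}

# empirical frequency with binomial stderr
prop_test_ok <- function(k, n, p, tol) abs(k / n - p) <= tol
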