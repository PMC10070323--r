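# Trial-wavefunction contract and analytic built-in families.
#
# A trial is evaluated in the log domain: sign and log-magnitude, with
# analytic per-electron gradients and Laplacians of log|psi|.  All ratios
# downstream (Metropolis, Green's function) are formed from log differences,
# so unnormalized magnitudes never overflow.

#' Construct a trial-wavefunction object
#'
#' The behavioral contract: `logpsi(X)` returns `list(sign, log)` for a
#' walker matrix `X` (one row per walker, `n_el * d` columns, electron-major
#' layout); `grad(X)` returns the per-coordinate gradient of `log|psi|`
#' (same shape as `X`); `lap(X)` returns the per-electron Laplacian of
#' `log|psi|` (`n_walkers x n_el`).  `param_grad(X)`, if present, returns
#' the derivative of `log|psi|` with respect to each free parameter
#' (`n_walkers x n_params`).
#'
#' @param name family identifier.
#' @param system owning `fndmc_system`.
#' @param params named numeric vector of free parameters (possibly empty).
#' @param logpsi,grad,lap,param_grad contract functions (see above).
#' @param nodeless `TRUE` when psi > 0 everywhere (implies exact nodes).
#' @param exact_node `TRUE` when the nodal set is analytically known.
#' @param exact_energy eigenvalue when the trial is an exact eigenstate,
#'   else `NA`.
#' @param antisymmetric whether same-spin exchange antisymmetry holds (model
#'   fixtures used only for nodal geometry may set this `FALSE`).
#' @param rebuild function `(params) -> trial` used by [set_trial_params()].
#' @return an object of class `fndmc_trial`.
#' @export
new_trial <- function(name, system, params, logpsi, grad, lap,
                      param_grad = NULL, nodeless = FALSE,
                      exact_node = nodeless, exact_energy = NA_real_,
                      antisymmetric = TRUE, rebuild = NULL) {
  structure(list(
    name = name, system = system, params = params,
    logpsi = logpsi, grad = grad, lap = lap, param_grad = param_grad,
    nodeless = nodeless, exact_node = exact_node,
    exact_energy = exact_energy, antisymmetric = antisymmetric,
    rebuild = rebuild
  ), class = "fndmc_trial")
}

#' @export
print.fndmc_trial <- function(x, ...) {
  cat("<fndmc_trial>", x$name, "on", x$system$label, "\n")
  if (length(x$params))
    cat("  params:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                           collapse = ", "), "\n")
  cat("  nodeless:", x$nodeless, " exact_node:", x$exact_node, "\n")
  invisible(x)
}

#' Replace the free parameters of a trial
#' @param trial a `fndmc_trial` with a rebuild rule.
#' @param params numeric vector (same length/order as `trial$params`).
#' @return a new `fndmc_trial`.
#' @export
set_trial_params <- function(trial, params) {
  if (is.null(trial$rebuild)) stop("trial has no free parameters")
  stopifnot(length(params) == length(trial$params))
  p <- stats::setNames(as.numeric(params), names(trial$params))
  trial$rebuild(p)
}

#' Local energy of configurations
#'
#' `E_L = -1/2 sum_i (lap_i log|psi| + |grad_i log|psi||^2) + V`, in
#' Hartree.  Constant for exact eigenstate trials (zero-variance
#' principle).
#'
#' @param trial a `fndmc_trial`.
#' @param system the owning `fndmc_system` (defaults to `trial$system`).
#' @param X a single configuration (numeric vector) or walker matrix.
#' @return numeric vector of local energies, one per walker.
#' @export
local_energy <- function(trial, system = trial$system, X) {
  X <- as_walker_matrix(X)
  if (min_particle_distance(system, X) <= 1e-12)
    stop("singular configuration: coincident particles")
  g <- trial$grad(X)
  l <- trial$lap(X)
  n <- n_electrons(system)
  d <- system$d
  g2 <- matrix(0, nrow(X), n)
  for (i in seq_len(n))
    g2[, i] <- rowSums(g[, d * (i - 1) + seq_len(d), drop = FALSE]^2)
  -0.5 * rowSums(l + g2) + potential_energy(system, X)
}

# smallest electron-electron / electron-nucleus distance over the batch
#' @keywords internal
min_particle_distance <- function(system, X) {
  n <- n_electrons(system)
  d <- system$d
  m <- Inf
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      xi <- X[, d * (i - 1) + seq_len(d), drop = FALSE]
      xj <- X[, d * (j - 1) + seq_len(d), drop = FALSE]
      m <- min(m, sqrt(min(rowSums((xi - xj)^2))))
    }
  }
  if (!is.null(system$nuclear_positions) && d == 3) {
    for (i in seq_len(n)) {
      xi <- X[, 3 * (i - 1) + 1:3, drop = FALSE]
      for (I in seq_along(system$nuclear_charges)) {
        dd <- sweep(xi, 2, system$nuclear_positions[I, ])
        m <- min(m, sqrt(min(rowSums(dd^2))))
      }
    }
  }
  m
}

#' Random configurations for spot checks (uses the current RNG stream)
#' @keywords internal
random_configs <- function(system, n_configs, sd = 1) {
  n <- n_electrons(system)
  d <- system$d
  X <- matrix(stats::rnorm(n_configs * n * d, sd = sd), n_configs, n * d)
  if (!is.null(system$nuclear_positions)) {
    centers <- rep_len(seq_along(system$nuclear_charges), n)
    for (i in seq_len(n))
      X[, d * (i - 1) + seq_len(d)] <- X[, d * (i - 1) + seq_len(d)] +
        matrix(system$nuclear_positions[centers[i], seq_len(d)],
               n_configs, d, byrow = TRUE)
  }
  X
}

#' Finite-difference check of a trial's derivatives
#'
#' Compares `grad` and `lap` against central finite differences of
#' `log|psi|` at random configurations.  Stencils that straddle a node
#' (sign change) are redrawn.
#'
#' @param trial a `fndmc_trial`.
#' @param n_configs number of random configurations.
#' @param h stencil width (bohr).
#' @param seed RNG seed.
#' @return list with `max_rel_grad`, `max_rel_lap` (worst relative
#'   deviations, with an absolute floor of 1e-8 in the denominator).
#' @export
check_derivatives <- function(trial, n_configs = 20, h = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sys <- trial$system
  nc <- n_electrons(sys) * sys$d
  worst_g <- 0; worst_l <- 0
  got <- 0; tries <- 0
  while (got < n_configs && tries < 20 * n_configs) {
    tries <- tries + 1
    x <- random_configs(sys, 1)
    s0 <- trial$logpsi(x)
    if (!is.finite(s0$log)) next
    g <- trial$grad(x); l <- trial$lap(x)
    # near nodes or coincidences the central stencil cannot resolve
    # log|psi| (truncation error ~ (h |grad|)^2), so redraw there
    if (max(abs(g)) > 2e-3 / h) next
    fd_g <- numeric(nc); fd_l2 <- numeric(nc)
    ok <- TRUE
    for (k in seq_len(nc)) {
      xp <- x; xm <- x
      xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
      sp <- trial$logpsi(xp); sm <- trial$logpsi(xm)
      if (sp$sign != s0$sign || sm$sign != s0$sign ||
          !is.finite(sp$log) || !is.finite(sm$log)) { ok <- FALSE; break }
      fd_g[k] <- (sp$log - sm$log) / (2 * h)
      fd_l2[k] <- (sp$log + sm$log - 2 * s0$log) / h^2
    }
    if (!ok) next
    got <- got + 1
    # per-electron Laplacian: sum second differences over that electron's coords
    d <- sys$d
    fd_l <- vapply(seq_len(n_electrons(sys)),
                   function(i) sum(fd_l2[d * (i - 1) + seq_len(d)]), 0)
    worst_g <- max(worst_g, abs(fd_g - as.numeric(g)) /
                              pmax(abs(fd_g), 1e-8 / h))
    worst_l <- max(worst_l, abs(fd_l - as.numeric(l)) / pmax(abs(fd_l), 1e-2))
  }
  if (got == 0) stop("could not find non-singular configurations")
  list(max_rel_grad = worst_g, max_rel_lap = worst_l, n_checked = got)
}

#' Antisymmetry spot test
#'
#' Swaps two random same-spin electrons and verifies the sign flips while
#' the log-magnitude is preserved.
#'
#' @param trial a `fndmc_trial`.
#' @param n_configs number of random transposition checks.
#' @param seed RNG seed.
#' @return largest absolute log-magnitude discrepancy (Inf if a sign failed
#'   to flip).
#' @export
check_antisymmetry <- function(trial, n_configs = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sys <- trial$system
  d <- sys$d
  blocks <- list(up = seq_len(sys$n_up), down = sys$n_up + seq_len(sys$n_down))
  blocks <- Filter(function(b) length(b) >= 2, blocks)
  if (!length(blocks)) return(0)
  worst <- 0
  for (rep in seq_len(n_configs)) {
    x <- random_configs(sys, 1)
    b <- blocks[[sample.int(length(blocks), 1)]]
    ij <- sample(b, 2)
    y <- x
    ci <- d * (ij[1] - 1) + seq_len(d); cj <- d * (ij[2] - 1) + seq_len(d)
    y[ci] <- x[cj]; y[cj] <- x[ci]
    s1 <- trial$logpsi(x); s2 <- trial$logpsi(y)
    if (!is.finite(s1$log) || !is.finite(s2$log)) next
    if (s1$sign * s2$sign != -1) return(Inf)
    worst <- max(worst, abs(s1$log - s2$log))
  }
  worst
}

#' @keywords internal
self_check_trial <- function(trial) {
  if (trial$antisymmetric) {
    a <- check_antisymmetry(trial, n_configs = 5)
    if (!is.finite(a) || a > 1e-9)
      stop("trial self-check failed: same-spin antisymmetry violated (",
           trial$name, ")")
  }
  dchk <- check_derivatives(trial, n_configs = 5)
  if (dchk$max_rel_grad > 1e-4 || dchk$max_rel_lap > 1e-3)
    stop(sprintf(
      "trial self-check failed: derivatives inconsistent with log|psi| (%s): grad %.2e lap %.2e",
      trial$name, dchk$max_rel_grad, dchk$max_rel_lap))
  trial
}

# ---------------------------------------------------------------------------
# Built-in analytic families

# electron i coordinate columns
.ecols <- function(i, d) d * (i - 1) + seq_len(d)

#' @keywords internal
trial_hydrogenic <- function(system, Z = 1) {
  stopifnot(n_electrons(system) == 1, system$d == 3)
  R0 <- system$nuclear_positions[1, ]
  build <- function(p) {
    Z <- p[["Z"]]
    rfun <- function(X) sqrt((X[, 1] - R0[1])^2 + (X[, 2] - R0[2])^2 +
                             (X[, 3] - R0[3])^2)
    new_trial(
      "hydrogenic", system, c(Z = Z),
      logpsi = function(X) {
        X <- as_walker_matrix(X)
        list(sign = rep(1, nrow(X)), log = -Z * rfun(X))
      },
      grad = function(X) {
        X <- as_walker_matrix(X)
        r <- rfun(X)
        -Z * sweep(X, 2, R0) / r
      },
      lap = function(X) {
        X <- as_walker_matrix(X)
        matrix(-2 * Z / rfun(X), ncol = 1)
      },
      param_grad = function(X) {
        X <- as_walker_matrix(X)
        matrix(-rfun(X), ncol = 1)
      },
      nodeless = TRUE,
      exact_energy = if (abs(Z - system$nuclear_charges[1]) < 1e-12)
        -Z^2 / 2 else NA_real_,
      rebuild = build
    )
  }
  build(c(Z = Z))
}

# product of hydrogenic 1s orbitals, each electron attached to a nucleus
# (round-robin); nodeless bosonic-symmetric guiding function used for
# well-separated H atoms
#' @keywords internal
trial_atomic_product <- function(system, zeta = NULL) {
  n <- n_electrons(system)
  stopifnot(system$d == 3)
  centers <- rep_len(seq_along(system$nuclear_charges), n)
  if (is.null(zeta)) zeta <- mean(system$nuclear_charges)
  build <- function(p) {
    z <- p[["zeta"]]
    R <- system$nuclear_positions
    rfun <- function(X, i) {
      ci <- .ecols(i, 3)
      sqrt((X[, ci[1]] - R[centers[i], 1])^2 +
           (X[, ci[2]] - R[centers[i], 2])^2 +
           (X[, ci[3]] - R[centers[i], 3])^2)
    }
    new_trial(
      "atomic_product", system, c(zeta = z),
      logpsi = function(X) {
        X <- as_walker_matrix(X)
        lg <- 0
        for (i in seq_len(n)) lg <- lg - z * rfun(X, i)
        list(sign = rep(1, nrow(X)), log = lg)
      },
      grad = function(X) {
        X <- as_walker_matrix(X)
        G <- matrix(0, nrow(X), 3 * n)
        for (i in seq_len(n)) {
          ci <- .ecols(i, 3)
          G[, ci] <- -z * sweep(X[, ci, drop = FALSE], 2, R[centers[i], ]) /
            rfun(X, i)
        }
        G
      },
      lap = function(X) {
        X <- as_walker_matrix(X)
        L <- matrix(0, nrow(X), n)
        for (i in seq_len(n)) L[, i] <- -2 * z / rfun(X, i)
        L
      },
      param_grad = function(X) {
        X <- as_walker_matrix(X)
        pg <- 0
        for (i in seq_len(n)) pg <- pg - rfun(X, i)
        matrix(pg, ncol = 1)
      },
      nodeless = TRUE, antisymmetric = FALSE, rebuild = build
    )
  }
  build(c(zeta = zeta))
}

# isotropic Gaussian, exact ground state of the non-interacting harmonic well
#' @keywords internal
trial_gauss_harmonic <- function(system, omega = 1) {
  n <- n_electrons(system); d <- system$d
  build <- function(p) {
    om <- p[["omega"]]
    new_trial(
      "gauss_harmonic", system, c(omega = om),
      logpsi = function(X) {
        X <- as_walker_matrix(X)
        list(sign = rep(1, nrow(X)), log = -0.5 * om * rowSums(X^2))
      },
      grad = function(X) -om * as_walker_matrix(X),
      lap = function(X) {
        X <- as_walker_matrix(X)
        matrix(-om * d, nrow(X), n)
      },
      param_grad = function(X) {
        X <- as_walker_matrix(X)
        matrix(-0.5 * rowSums(X^2), ncol = 1)
      },
      nodeless = TRUE, antisymmetric = (n == 1),
      exact_energy = n * om * d / 2,
      rebuild = build
    )
  }
  build(c(omega = omega))
}

# two same-spin fermions in a 1-D harmonic well.  The node is the line
# a1*x1 + a2*x2 = c; (alpha = 0, delta = 0) is the exact antisymmetric
# ground state (x1 - x2) exp(-omega (x1^2 + x2^2)/2) with energy 2*omega.
# alpha rotates the node away from x1 = x2; delta offsets it.
#' @keywords internal
trial_harmonic1d2f <- function(system, omega = 1, alpha = 0, delta = 0) {
  stopifnot(system$d == 1, n_electrons(system) == 2)
  build <- function(p) {
    om <- p[["omega"]]; al <- p[["alpha"]]; de <- p[["delta"]]
    a1 <- (cos(al) + sin(al)) / sqrt(2)
    a2 <- (-cos(al) + sin(al)) / sqrt(2)
    exact <- abs(al) < 1e-14 && abs(de) < 1e-14
    new_trial(
      "harmonic1d2f", system, c(omega = om, alpha = al, delta = de),
      logpsi = function(X) {
        X <- as_walker_matrix(X)
        u <- a1 * X[, 1] + a2 * X[, 2] - de
        list(sign = sign(u), log = log(abs(u)) - 0.5 * om * rowSums(X^2))
      },
      grad = function(X) {
        X <- as_walker_matrix(X)
        u <- a1 * X[, 1] + a2 * X[, 2] - de
        cbind(a1 / u - om * X[, 1], a2 / u - om * X[, 2])
      },
      lap = function(X) {
        X <- as_walker_matrix(X)
        u <- a1 * X[, 1] + a2 * X[, 2] - de
        cbind(-a1^2 / u^2 - om, -a2^2 / u^2 - om)
      },
      nodeless = FALSE, exact_node = TRUE,
      antisymmetric = exact,
      exact_energy = if (exact) 2 * om else NA_real_,
      rebuild = build
    )
  }
  build(c(omega = omega, alpha = alpha, delta = delta))
}

# single particle with a hyperplane node: psi = (n . x - c) exp(-|x|^2/2)
#' @keywords internal
trial_linear_node <- function(system, normal, offset = 0) {
  stopifnot(n_electrons(system) == 1)
  d <- system$d
  normal <- as.numeric(normal)
  stopifnot(length(normal) == d)
  u_of <- function(X) as.numeric(X %*% normal) - offset
  new_trial(
    "linear_node", system,
    stats::setNames(numeric(0), character(0)),
    logpsi = function(X) {
      X <- as_walker_matrix(X)
      u <- u_of(X)
      list(sign = sign(u), log = log(abs(u)) - 0.5 * rowSums(X^2))
    },
    grad = function(X) {
      X <- as_walker_matrix(X)
      u <- u_of(X)
      outer(1 / u, normal) - X
    },
    lap = function(X) {
      X <- as_walker_matrix(X)
      u <- u_of(X)
      matrix(-sum(normal^2) / u^2 - d, ncol = 1)
    },
    nodeless = FALSE, exact_node = TRUE, antisymmetric = FALSE
  )
}

# two-electron Pade-Jastrow for helium-like ions:
# psi = exp(-Z (r1 + r2)) * exp(u / (2 (1 + b u))), u = r12.
# Nodeless; satisfies the nuclear cusp (-Z) and the antiparallel
# electron-electron cusp (+1/2) for every b.
#' @keywords internal
trial_he_pade <- function(system, b = 0.35, Z = NULL) {
  stopifnot(n_electrons(system) == 2, system$d == 3,
            length(system$nuclear_charges) == 1)
  if (is.null(Z)) Z <- system$nuclear_charges[1]
  R0 <- system$nuclear_positions[1, ]
  build <- function(p) {
    b <- p[["b"]]; Z <- p[["Z"]]
    parts <- function(X) {
      x1 <- sweep(X[, 1:3, drop = FALSE], 2, R0)
      x2 <- sweep(X[, 4:6, drop = FALSE], 2, R0)
      r1 <- sqrt(rowSums(x1^2)); r2 <- sqrt(rowSums(x2^2))
      dv <- x1 - x2
      u <- sqrt(rowSums(dv^2))
      list(x1 = x1, x2 = x2, r1 = r1, r2 = r2, dv = dv, u = u)
    }
    tr <- new_trial(
      "he_pade", system, c(b = b, Z = Z),
      logpsi = function(X) {
        X <- as_walker_matrix(X)
        p <- parts(X)
        list(sign = rep(1, nrow(X)),
             log = -Z * (p$r1 + p$r2) + p$u / (2 * (1 + b * p$u)))
      },
      grad = function(X) {
        X <- as_walker_matrix(X)
        p <- parts(X)
        jp <- 1 / (2 * (1 + b * p$u)^2)          # J'(u)
        g1 <- -Z * p$x1 / p$r1 + jp * p$dv / p$u
        g2 <- -Z * p$x2 / p$r2 - jp * p$dv / p$u
        cbind(g1, g2)
      },
      lap = function(X) {
        X <- as_walker_matrix(X)
        p <- parts(X)
        jp <- 1 / (2 * (1 + b * p$u)^2)
        jpp <- -b / (1 + b * p$u)^3              # J''(u)
        lj <- jpp + 2 * jp / p$u                 # radial Laplacian of J
        cbind(-2 * Z / p$r1 + lj, -2 * Z / p$r2 + lj)
      },
      param_grad = function(X) {
        X <- as_walker_matrix(X)
        p <- parts(X)
        cbind(-p$u^2 / (2 * (1 + b * p$u)^2),    # d/db
              -(p$r1 + p$r2))                    # d/dZ
      },
      nodeless = TRUE, antisymmetric = FALSE, rebuild = build
    )
    # fused evaluation: the shared distance work is done once per DMC step
    tr$full <- function(X) {
    X <- as_walker_matrix(X)
    x1 <- sweep(X[, 1:3, drop = FALSE], 2, R0)
    x2 <- sweep(X[, 4:6, drop = FALSE], 2, R0)
    r1 <- sqrt(rowSums(x1^2)); r2 <- sqrt(rowSums(x2^2))
    dv <- x1 - x2
    u <- sqrt(rowSums(dv^2))
    den <- 1 + b * u
    jp <- 1 / (2 * den^2)
    jpp <- -b / den^3
    lj <- jpp + 2 * jp / u
    g1 <- -Z * x1 / r1 + jp * dv / u
    g2 <- -Z * x2 / r2 - jp * dv / u
    list(sign = rep(1, nrow(X)),
         log = -Z * (r1 + r2) + u / (2 * den),
         grad = cbind(g1, g2),
         lap = cbind(-2 * Z / r1 + lj, -2 * Z / r2 + lj))
    }
    tr
  }
  build(c(b = b, Z = Z))
}

#' Construct a built-in trial wavefunction
#'
#' Families:
#' \describe{
#'   \item{`hydrogenic`}{single electron, `psi = exp(-Z r)`; param `Z`.}
#'   \item{`atomic_product`}{product of 1s orbitals, one electron per
#'     nucleus round-robin; param `zeta`.  Nodeless guiding function for
#'     well-separated hydrogen atoms.}
#'   \item{`gauss_harmonic`}{product Gaussian `exp(-omega |x|^2 / 2)`, the
#'     exact ground state of the non-interacting harmonic well.}
#'   \item{`harmonic1d2f`}{two same-spin 1-D fermions,
#'     `u * exp(-omega(x1^2 + x2^2)/2)` with node line controlled by
#'     `alpha` (rotation) and `delta` (offset); exact at
#'     `alpha = delta = 0`.}
#'   \item{`linear_node`}{single particle with hyperplane node
#'     `(normal . x - offset)` times a Gaussian envelope.}
#'   \item{`he_pade`}{two-electron Pade-Jastrow
#'     `exp(-Z(r1 + r2)) exp(u / (2(1 + b u)))`; params `b`, `Z`.}
#'   \item{`slater_jastrow`}{single Slater determinant of STO orbitals per
#'     spin channel times a cusp-correct electron-electron Pade Jastrow
#'     (see [make_slater_jastrow()]).}
#'   \item{`neural`}{a compact two-hidden-layer per-electron network
#'     feeding a few determinants with STO envelopes (see
#'     [make_neural_trial()]).}
#' }
#'
#' Every constructed trial passes a self-check (antisymmetry spot test plus
#' finite-difference derivative consistency); failures raise an error naming
#' the violated invariant.
#'
#' @param name family identifier.
#' @param system owning `fndmc_system`.
#' @param params list of family parameters (see above).
#' @param self_check run the construction self-check (default `TRUE`).
#' @return a `fndmc_trial`.
#' @export
make_trial <- function(name, system, params = list(), self_check = TRUE) {
  tr <- switch(
    name,
    hydrogenic = trial_hydrogenic(system, Z = params$Z %||% 1),
    atomic_product = trial_atomic_product(system, zeta = params$zeta),
    gauss_harmonic = trial_gauss_harmonic(system, omega = params$omega %||% 1),
    harmonic1d2f = trial_harmonic1d2f(system, omega = params$omega %||% 1,
                                      alpha = params$alpha %||% 0,
                                      delta = params$delta %||% 0),
    linear_node = trial_linear_node(system, normal = params$normal,
                                    offset = params$offset %||% 0),
    he_pade = trial_he_pade(system, b = params$b %||% 0.35, Z = params$Z),
    slater_jastrow = make_slater_jastrow(system, params),
    neural = do.call(make_neural_trial, c(list(system = system), params)),
    stop("unknown trial family: ", name)
  )
  if (self_check) self_check_trial(tr) else tr
}

#' Kato cusp-condition diagnostic
#'
#' Numerically estimates the logarithmic derivative of the trial at small
#' electron-nucleus and (antiparallel) electron-electron separations and
#' compares with the Kato values `-Z` and `+1/2`.  Cusp violations inflate
#' the local-energy variance, so this is a useful pre-run diagnostic.
#'
#' @param trial a `fndmc_trial`.
#' @param system owning system (defaults to `trial$system`).
#' @param r_small radii at which the spherically averaged log-magnitude is
#'   evaluated (bohr); a quadratic fit through them extrapolates the
#'   log-derivative to zero separation.
#' @param n_dirs directions averaged per radius.
#' @param seed RNG seed for the direction draw.
#' @return list with components `nuclear` (data frame: nucleus, Z,
#'   estimate, expected, violation flag) and `electron_pair` (estimate,
#'   expected 0.5, violation flag); `NULL` entries where not applicable.
#' @export
cusp_check <- function(trial, system = trial$system,
                       r_small = c(5e-4, 1e-3, 1.5e-3), n_dirs = 24, seed = 1) {
  set.seed(seed)
  d <- system$d
  if (d != 3) stop("cusp_check requires a 3-D system")
  n <- n_electrons(system)
  half <- matrix(stats::rnorm(ceiling(n_dirs / 2) * 3), ncol = 3)
  half <- half / sqrt(rowSums(half^2))
  dirs <- rbind(half, -half)      # antithetic pairs cancel odd-order terms
  n_dirs <- nrow(dirs)
  base <- random_configs(system, 1)
  logmean <- function(X) mean(trial$logpsi(X)$log)
  # derivative at r = 0 from a quadratic fit (removes the O(r) curvature term)
  slope0 <- function(lg) unname(stats::coef(stats::lm(lg ~ r_small + I(r_small^2)))[2])
  nuclear <- NULL
  if (!is.null(system$nuclear_positions)) {
    est <- numeric(length(system$nuclear_charges))
    for (I in seq_along(system$nuclear_charges)) {
      lg <- vapply(r_small, function(rr) {
        Xs <- matrix(rep(base, each = n_dirs), n_dirs)
        Xs[, 1:3] <- sweep(rr * dirs, 2, system$nuclear_positions[I, ], "+")
        logmean(Xs)
      }, 0)
      est[I] <- slope0(lg)
    }
    nuclear <- data.frame(nucleus = seq_along(est),
                          Z = system$nuclear_charges,
                          estimate = est, expected = -system$nuclear_charges,
                          violated = abs(est + system$nuclear_charges) > 0.05)
  }
  pair <- NULL
  if (trial$system$n_up >= 1 && trial$system$n_down >= 1) {
    j <- system$n_up + 1                      # first spin-down electron
    lg <- vapply(r_small, function(rr) {
      Xs <- matrix(rep(base, each = n_dirs), n_dirs)
      Xs[, .ecols(j, 3)] <- sweep(rr * dirs, 2, base[1:3], "+")
      logmean(Xs)
    }, 0)
    est <- slope0(lg)
    pair <- list(estimate = est, expected = 0.5,
                 violated = abs(est - 0.5) > 0.05)
  }
  list(nuclear = nuclear, electron_pair = pair)
}
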