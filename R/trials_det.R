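# Determinant-based trials: Slater-Jastrow with STO orbitals and a compact
# neural ansatz (per-electron network feeding a few determinants).
#
# For a sum of determinants Psi = sum_d c_d D_d(up) D_d(down) exp(J), the
# per-electron derivatives of log|Psi| follow from the single-row structure
# of electron moves: with q_di = sum_k inv_d[k,i] grad phi_dk(r_i) and
# L_di = sum_k inv_d[k,i] lap phi_dk(r_i),
#   grad_i log|Psi| = sum_d w_d q_di + grad_i J
#   lap_i  log|Psi| = sum_d w_d L_di - |sum_d w_d q_di|^2 + lap_i J
# where w_d are the signed determinant weights normalised to sum to 1.

# ---------------------------------------------------------------------------
# block evaluation: sign/log-magnitude of one spin determinant plus the
# q_di / L_di contractions.  `ev` is a list over electrons j of orbital
# evaluations: list(val, gx, gy, gz, lap), each W x nb.
det_block <- function(ev) {
  nb <- length(ev)
  W <- nrow(ev[[1]]$val)
  if (nb == 1) {
    v <- ev[[1]]$val[, 1]
    inv <- 1 / v
    q <- list(cbind(inv * ev[[1]]$gx[, 1], inv * ev[[1]]$gy[, 1],
                    inv * ev[[1]]$gz[, 1]))
    return(list(sign = sign(v), logabs = log(abs(v)), q = q,
                L = matrix(inv * ev[[1]]$lap[, 1], ncol = 1),
                inv = list(matrix(inv, ncol = 1))))
  }
  if (nb == 2) {
    a <- ev[[1]]$val[, 1]; b <- ev[[1]]$val[, 2]
    cc <- ev[[2]]$val[, 1]; dd <- ev[[2]]$val[, 2]
    det <- a * dd - b * cc
    # inv[k, i] of Phi[i, k]: row i = electron, col k = orbital
    i11 <- dd / det; i21 <- -cc / det; i12 <- -b / det; i22 <- a / det
    q <- vector("list", 2)
    q[[1]] <- cbind(i11 * ev[[1]]$gx[, 1] + i21 * ev[[1]]$gx[, 2],
                    i11 * ev[[1]]$gy[, 1] + i21 * ev[[1]]$gy[, 2],
                    i11 * ev[[1]]$gz[, 1] + i21 * ev[[1]]$gz[, 2])
    q[[2]] <- cbind(i12 * ev[[2]]$gx[, 1] + i22 * ev[[2]]$gx[, 2],
                    i12 * ev[[2]]$gy[, 1] + i22 * ev[[2]]$gy[, 2],
                    i12 * ev[[2]]$gz[, 1] + i22 * ev[[2]]$gz[, 2])
    L <- cbind(i11 * ev[[1]]$lap[, 1] + i21 * ev[[1]]$lap[, 2],
               i12 * ev[[2]]$lap[, 1] + i22 * ev[[2]]$lap[, 2])
    return(list(sign = sign(det), logabs = log(abs(det)), q = q, L = L,
                inv = list(cbind(i11, i12), cbind(i21, i22))))
  }
  # general path: per-walker LU
  sgn <- numeric(W); lg <- numeric(W)
  q <- lapply(seq_len(nb), function(j) matrix(0, W, 3))
  L <- matrix(0, W, nb)
  invs <- lapply(seq_len(nb), function(k) matrix(0, W, nb))  # inv[k, i]
  Phi <- matrix(0, nb, nb)
  for (w in seq_len(W)) {
    for (j in seq_len(nb)) Phi[j, ] <- ev[[j]]$val[w, ]
    dqr <- determinant(Phi, logarithm = TRUE)
    sgn[w] <- dqr$sign
    lg[w] <- as.numeric(dqr$modulus)
    inv <- tryCatch(solve(Phi), error = function(e) matrix(NA_real_, nb, nb))
    for (k in seq_len(nb)) invs[[k]][w, ] <- inv[k, ]
    for (j in seq_len(nb)) {
      q[[j]][w, ] <- c(sum(inv[, j] * ev[[j]]$gx[w, ]),
                       sum(inv[, j] * ev[[j]]$gy[w, ]),
                       sum(inv[, j] * ev[[j]]$gz[w, ]))
      L[w, j] <- sum(inv[, j] * ev[[j]]$lap[w, ])
    }
  }
  list(sign = sgn, logabs = lg, q = q, L = L, inv = invs)
}

# ---------------------------------------------------------------------------
# electron-electron Pade Jastrow with Kato cusps:
# J = sum_{i<j} gamma_ij u / (1 + b_ij u), gamma = 1/2 antiparallel,
# 1/4 parallel.  Returns val/grad/lap and d/db gradients.
pade_jastrow_eval <- function(X, n_up, n_down, b_para, b_anti,
                              want_pgrad = FALSE) {
  n <- n_up + n_down
  W <- nrow(X)
  val <- numeric(W)
  G <- matrix(0, W, 3 * n)
  L <- matrix(0, W, n)
  dpara <- numeric(W); danti <- numeric(W)
  spin <- rep(c(1L, 2L), c(n_up, n_down))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- spin[i] == spin[j]
    gam <- if (same) 0.25 else 0.5
    b <- if (same) b_para else b_anti
    ci <- 3 * (i - 1) + 1:3; cj <- 3 * (j - 1) + 1:3
    dv <- X[, ci, drop = FALSE] - X[, cj, drop = FALSE]
    u <- sqrt(rowSums(dv^2))
    den <- 1 + b * u
    val <- val + gam * u / den
    jp <- gam / den^2
    jl <- -2 * gam * b / den^3 + 2 * jp / u
    gv <- jp * dv / u
    G[, ci] <- G[, ci] + gv
    G[, cj] <- G[, cj] - gv
    L[, i] <- L[, i] + jl
    L[, j] <- L[, j] + jl
    if (want_pgrad) {
      db <- -gam * u^2 / den^2
      if (same) dpara <- dpara + db else danti <- danti + db
    }
  }
  out <- list(val = val, grad = G, lap = L)
  if (want_pgrad) out$pgrad <- cbind(b_para = dpara, b_anti = danti)
  out
}

# ---------------------------------------------------------------------------
# STO orbital sets.  An orbital is list(type, zeta, a, axis); types:
#   "1s": exp(-zeta r); "2s": (1 - a r) exp(-zeta r);
#   "2p": axis-coordinate * exp(-zeta r)  (axis in 1:3)
sto_orbital_eval <- function(orbs, E, center) {
  W <- nrow(E)
  K <- length(orbs)
  x <- sweep(E, 2, center)
  r <- sqrt(rowSums(x^2))
  val <- gx <- gy <- gz <- lap <- matrix(0, W, K)
  for (k in seq_len(K)) {
    o <- orbs[[k]]
    z <- o$zeta
    e <- exp(-z * r)
    if (o$type == "1s") {
      f <- e; fp <- -z * e; fl <- (z^2 - 2 * z / r) * e
      val[, k] <- f
      gx[, k] <- fp * x[, 1] / r; gy[, k] <- fp * x[, 2] / r
      gz[, k] <- fp * x[, 3] / r
      lap[, k] <- fl
    } else if (o$type == "2s") {
      a <- o$a
      f <- (1 - a * r) * e
      fp <- (-a - z * (1 - a * r)) * e
      fpp <- (2 * a * z + z^2 - a * z^2 * r) * e
      val[, k] <- f
      gx[, k] <- fp * x[, 1] / r; gy[, k] <- fp * x[, 2] / r
      gz[, k] <- fp * x[, 3] / r
      lap[, k] <- fpp + 2 * fp / r
    } else if (o$type == "2p") {
      ax <- o$axis
      xc <- x[, ax]
      val[, k] <- xc * e
      base <- -z * xc * e / r
      gx[, k] <- base * x[, 1]; gy[, k] <- base * x[, 2]
      gz[, k] <- base * x[, 3]
      if (ax == 1) gx[, k] <- base * x[, 1] + e
      if (ax == 2) gy[, k] <- base * x[, 2] + e
      if (ax == 3) gz[, k] <- base * x[, 3] + e
      lap[, k] <- xc * e * (z^2 - 4 * z / r)
    } else stop("unknown STO type: ", o$type)
  }
  list(val = val, gx = gx, gy = gy, gz = gz, lap = lap)
}

# minimal-basis shell filling with Slater screening rules
sto_default_orbitals <- function(Z, n_occ) {
  shells <- list(list(type = "1s"), list(type = "2s"),
                 list(type = "2p", axis = 1), list(type = "2p", axis = 2),
                 list(type = "2p", axis = 3))
  if (n_occ > length(shells))
    stop("default STO basis supports at most 5 same-spin electrons")
  z1s <- max(Z - 0.3125, 0.65)
  n2 <- max(0, min(Z, 10) - 2)
  z2 <- max((Z - 2 * 0.85 - max(n2 - 1, 0) * 0.35) / 2, 0.45)
  lapply(shells[seq_len(n_occ)], function(sh) {
    if (sh$type == "1s") list(type = "1s", zeta = z1s)
    else if (sh$type == "2s") list(type = "2s", zeta = z2, a = z2)
    else list(type = "2p", zeta = z2, axis = sh$axis)
  })
}

#' Single-determinant Slater-Jastrow trial for atoms
#'
#' One Slater determinant per spin channel built from a minimal STO basis
#' (Slater screening exponents by default) multiplied by a cusp-correct
#' electron-electron Pade Jastrow.  Free parameters: the Jastrow widths
#' `b_para` and `b_anti`.
#'
#' @param system a single-atom `fndmc_system` (up to 5 electrons per spin).
#' @param params optional list: `b_para`, `b_anti` (Jastrow widths, bohr^-1),
#'   `orbitals_up` / `orbitals_down` (explicit orbital lists overriding the
#'   defaults; each orbital is `list(type, zeta, a, axis)`).
#' @return a `fndmc_trial`.
#' @export
make_slater_jastrow <- function(system, params = list()) {
  if (is.null(system$nuclear_positions) || length(system$nuclear_charges) != 1)
    stop("slater_jastrow requires a single-atom system")
  Z <- system$nuclear_charges[1]
  center <- system$nuclear_positions[1, ]
  nu <- system$n_up; nd <- system$n_down
  orbs_up <- params$orbitals_up %||% sto_default_orbitals(Z, nu)
  orbs_down <- if (nd > 0) params$orbitals_down %||% sto_default_orbitals(Z, nd)
               else NULL
  build <- function(p) {
    b_para <- p[["b_para"]]; b_anti <- p[["b_anti"]]
    n <- nu + nd
    eval_parts <- function(X) {
      evu <- lapply(seq_len(nu), function(j)
        sto_orbital_eval(orbs_up, X[, 3 * (j - 1) + 1:3, drop = FALSE], center))
      bu <- det_block(evu)
      bd <- NULL
      if (nd > 0) {
        evd <- lapply(seq_len(nd), function(j)
          sto_orbital_eval(orbs_down,
                           X[, 3 * (nu + j - 1) + 1:3, drop = FALSE], center))
        bd <- det_block(evd)
      }
      list(bu = bu, bd = bd)
    }
    new_trial(
      "slater_jastrow", system, c(b_para = b_para, b_anti = b_anti),
      logpsi = function(X) {
        X <- as_walker_matrix(X)
        pr <- eval_parts(X)
        jj <- pade_jastrow_eval(X, nu, nd, b_para, b_anti)
        sgn <- pr$bu$sign; lg <- pr$bu$logabs
        if (!is.null(pr$bd)) { sgn <- sgn * pr$bd$sign; lg <- lg + pr$bd$logabs }
        list(sign = sgn, log = lg + jj$val)
      },
      grad = function(X) {
        X <- as_walker_matrix(X)
        pr <- eval_parts(X)
        jj <- pade_jastrow_eval(X, nu, nd, b_para, b_anti)
        G <- jj$grad
        for (j in seq_len(nu)) G[, 3 * (j - 1) + 1:3] <-
          G[, 3 * (j - 1) + 1:3] + pr$bu$q[[j]]
        if (nd > 0) for (j in seq_len(nd)) G[, 3 * (nu + j - 1) + 1:3] <-
          G[, 3 * (nu + j - 1) + 1:3] + pr$bd$q[[j]]
        G
      },
      lap = function(X) {
        X <- as_walker_matrix(X)
        pr <- eval_parts(X)
        jj <- pade_jastrow_eval(X, nu, nd, b_para, b_anti)
        L <- jj$lap
        # single determinant: lap_i log|D| = L_di - |q_di|^2
        for (j in seq_len(nu)) L[, j] <-
          L[, j] + pr$bu$L[, j] - rowSums(pr$bu$q[[j]]^2)
        if (nd > 0) for (j in seq_len(nd)) L[, nu + j] <-
          L[, nu + j] + pr$bd$L[, j] - rowSums(pr$bd$q[[j]]^2)
        L
      },
      param_grad = function(X) {
        X <- as_walker_matrix(X)
        pade_jastrow_eval(X, nu, nd, b_para, b_anti, want_pgrad = TRUE)$pgrad
      },
      nodeless = (nu <= 1 && nd <= 1),
      exact_node = (nu <= 1 && nd <= 1),
      rebuild = build
    )
  }
  build(c(b_para = params$b_para %||% 1, b_anti = params$b_anti %||% 1))
}
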