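# Compact neural trial wavefunction for single atoms.
#
# Each electron is mapped independently through a small two-hidden-layer
# tanh network (a per-electron map is trivially permutation-equivariant);
# per-determinant linear heads with STO envelopes exp(-alpha r) produce
# orbital matrices, and a few determinants per spin channel are summed and
# multiplied by a cusp-correct electron-electron Pade Jastrow.  All spatial
# derivatives are propagated analytically (forward mode), and parameter
# gradients of log|psi| are obtained by reverse mode for the VMC optimizer.
#
# This ansatz is deliberately CPU-sized: it exists to exercise the
# VMC-train -> DMC workflow, not to reach the accuracy of large
# GPU-trained networks.

neural_shapes <- function(F_in, H1, H2, K_up, K_down, D) {
  sh <- list(W1 = c(H1, F_in), b1 = H1, W2 = c(H2, H1), b2 = H2)
  for (d in seq_len(D)) {
    sh[[paste0("V_up_", d)]] <- c(K_up, H2)
    sh[[paste0("c_up_", d)]] <- K_up
    sh[[paste0("la_up_", d)]] <- K_up
    if (K_down > 0) {
      sh[[paste0("V_down_", d)]] <- c(K_down, H2)
      sh[[paste0("c_down_", d)]] <- K_down
      sh[[paste0("la_down_", d)]] <- K_down
    }
  }
  sh$cdet <- D
  sh$jb <- 2
  sh
}

neural_unflatten <- function(theta, shapes) {
  out <- list()
  pos <- 0
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    len <- prod(s)
    v <- theta[pos + seq_len(len)]
    out[[nm]] <- if (length(s) == 2) matrix(v, s[1], s[2]) else v
    pos <- pos + len
  }
  stopifnot(pos == length(theta))
  out
}

neural_flatten <- function(w, shapes) {
  unlist(lapply(names(shapes), function(nm) as.numeric(w[[nm]])),
         use.names = FALSE)
}

neural_init <- function(F_in, H1, H2, K_up, K_down, D, Z, seed) {
  set.seed(seed)
  sc <- function(n, m) matrix(stats::rnorm(n * m, sd = 1 / sqrt(m)), n, m)
  w <- list(W1 = sc(H1, F_in), b1 = stats::rnorm(H1, sd = 0.1),
            W2 = sc(H2, H1), b2 = stats::rnorm(H2, sd = 0.1))
  z_up <- vapply(sto_default_orbitals(Z, max(K_up, 1)), `[[`, 0, "zeta")
  z_dn <- if (K_down > 0)
    vapply(sto_default_orbitals(Z, K_down), `[[`, 0, "zeta") else numeric(0)
  for (d in seq_len(D)) {
    jit <- if (d == 1) 0 else 0.1
    w[[paste0("V_up_", d)]] <- sc(K_up, H2) * 0.3
    w[[paste0("c_up_", d)]] <- rep(1, K_up) + stats::rnorm(K_up, sd = jit)
    w[[paste0("la_up_", d)]] <- log(z_up[seq_len(K_up)]) +
      stats::rnorm(K_up, sd = jit)
    if (K_down > 0) {
      w[[paste0("V_down_", d)]] <- sc(K_down, H2) * 0.3
      w[[paste0("c_down_", d)]] <- rep(1, K_down) + stats::rnorm(K_down, sd = jit)
      w[[paste0("la_down_", d)]] <- log(z_dn) + stats::rnorm(K_down, sd = jit)
    }
  }
  w$cdet <- c(1, rep(0.25, D - 1))
  w$jb <- c(1, 1)          # b_para, b_anti
  w
}

# forward pass of the trunk for one electron's batch of positions (W x 3).
# Returns value, three spatial tangents, Laplacian channel and caches.
neural_trunk <- function(E, center, w, want_derivs) {
  x <- sweep(E, 2, center)
  r <- sqrt(rowSums(x^2))
  f <- cbind(x, r)
  z1 <- f %*% t(w$W1) + matrix(w$b1, nrow(E), length(w$b1), byrow = TRUE)
  h1 <- tanh(z1)
  z2 <- h1 %*% t(w$W2) + matrix(w$b2, nrow(E), length(w$b2), byrow = TRUE)
  h2 <- tanh(z2)
  out <- list(x = x, r = r, f = f, h1 = h1, h2 = h2)
  if (!want_derivs) return(out)
  t1 <- 1 - h1^2; t2 <- 1 - h2^2
  # feature tangents d f / d x_c and feature Laplacian
  fg <- lapply(1:3, function(cc) {
    m <- matrix(0, nrow(E), 4)
    m[, cc] <- 1
    m[, 4] <- x[, cc] / r
    m
  })
  flap <- cbind(matrix(0, nrow(E), 3), 2 / r)
  z1g <- lapply(fg, function(m) m %*% t(w$W1))
  h1g <- lapply(z1g, function(zg) t1 * zg)
  z1sq <- Reduce(`+`, lapply(z1g, function(zg) zg^2))
  h1lap <- t1 * (flap %*% t(w$W1)) + (-2 * h1 * t1) * z1sq
  z2g <- lapply(h1g, function(hg) hg %*% t(w$W2))
  h2g <- lapply(z2g, function(zg) t2 * zg)
  z2sq <- Reduce(`+`, lapply(z2g, function(zg) zg^2))
  h2lap <- t2 * (h1lap %*% t(w$W2)) + (-2 * h2 * t2) * z2sq
  out$t1 <- t1; out$t2 <- t2
  out$h1g <- h1g; out$h1lap <- h1lap
  out$h2g <- h2g; out$h2lap <- h2lap
  out
}

# orbital head: phi_k = (V h2 + c)_k * exp(-alpha_k r)
neural_head <- function(tr, V, cc, la, want_derivs) {
  W <- length(tr$r)
  K <- length(cc)
  o <- tr$h2 %*% t(V) + matrix(cc, W, K, byrow = TRUE)
  alpha <- exp(la)
  env <- exp(-outer(tr$r, alpha))
  val <- o * env
  out <- list(val = val, o = o, env = env, alpha = alpha)
  if (!want_derivs) return(out)
  og <- lapply(tr$h2g, function(hg) hg %*% t(V))
  olap <- tr$h2lap %*% t(V)
  am <- matrix(alpha, W, K, byrow = TRUE)
  xr <- tr$x / tr$r
  envg <- lapply(1:3, function(ccd) -am * xr[, ccd] * env)
  envlap <- (am^2 - 2 * am / tr$r) * env
  gx <- og[[1]] * env + o * envg[[1]]
  gy <- og[[2]] * env + o * envg[[2]]
  gz <- og[[3]] * env + o * envg[[3]]
  lap <- olap * env + 2 * (og[[1]] * envg[[1]] + og[[2]] * envg[[2]] +
                           og[[3]] * envg[[3]]) + o * envlap
  out$gx <- gx; out$gy <- gy; out$gz <- gz; out$lap <- lap
  out
}

# full evaluation; want: "log" (sign/log only), "derivs" (plus grad/lap),
# "pgrad" (plus per-walker parameter gradients of log|psi|)
neural_eval <- function(X, sysinfo, w, want = "derivs") {
  want_derivs <- want != "log"
  nu <- sysinfo$n_up; nd <- sysinfo$n_down
  n <- nu + nd
  D <- sysinfo$D
  W <- nrow(X)
  center <- sysinfo$center
  trunks <- lapply(seq_len(n), function(j)
    neural_trunk(X[, 3 * (j - 1) + 1:3, drop = FALSE], center, w, want_derivs))
  heads <- vector("list", D)
  blocks <- vector("list", D)
  for (d in seq_len(D)) {
    hu <- lapply(seq_len(nu), function(j)
      neural_head(trunks[[j]], w[[paste0("V_up_", d)]],
                  w[[paste0("c_up_", d)]], w[[paste0("la_up_", d)]],
                  want_derivs))
    bu <- det_block(hu)
    hd <- NULL; bd <- NULL
    if (nd > 0) {
      hd <- lapply(seq_len(nd), function(j)
        neural_head(trunks[[nu + j]], w[[paste0("V_down_", d)]],
                    w[[paste0("c_down_", d)]], w[[paste0("la_down_", d)]],
                    want_derivs))
      bd <- det_block(hd)
    }
    heads[[d]] <- list(up = hu, down = hd)
    blocks[[d]] <- list(up = bu, down = bd)
  }
  # combine determinants in the log domain
  lg_d <- sapply(seq_len(D), function(d) {
    lg <- blocks[[d]]$up$logabs
    if (nd > 0) lg <- lg + blocks[[d]]$down$logabs
    lg + log(abs(w$cdet[d]))
  })
  sg_d <- sapply(seq_len(D), function(d) {
    s <- blocks[[d]]$up$sign * sign(w$cdet[d])
    if (nd > 0) s <- s * blocks[[d]]$down$sign
    s
  })
  lg_d <- matrix(lg_d, W, D); sg_d <- matrix(sg_d, W, D)
  M <- apply(lg_d, 1, max)
  terms <- sg_d * exp(lg_d - M)
  S <- rowSums(terms)
  logpsi_det <- M + log(abs(S))
  sign_det <- sign(S)
  wd <- terms / S                              # signed weights, rows sum to 1
  jj <- pade_jastrow_eval(X, nu, nd, w$jb[1], w$jb[2],
                          want_pgrad = (want == "pgrad"))
  out <- list(sign = sign_det, log = logpsi_det + jj$val)
  if (!want_derivs) return(out)
  G <- jj$grad
  L <- jj$lap
  for (i in seq_len(n)) {
    up <- i <= nu
    jloc <- if (up) i else i - nu
    qi <- matrix(0, W, 3)
    Li <- numeric(W)
    for (d in seq_len(D)) {
      b <- if (up) blocks[[d]]$up else blocks[[d]]$down
      qi <- qi + wd[, d] * b$q[[jloc]]
      Li <- Li + wd[, d] * b$L[, jloc]
    }
    cols <- 3 * (i - 1) + 1:3
    G[, cols] <- G[, cols] + qi
    L[, i] <- L[, i] + Li - rowSums(qi^2)
  }
  out$grad <- G
  out$lap <- L
  if (want != "pgrad") return(out)
  # ---- reverse mode: per-walker d log|psi| / d theta -----------------------
  shapes <- sysinfo$shapes
  PG <- matrix(0, W, sysinfo$n_params)
  idx <- sysinfo$idx
  add <- function(nm, val) PG[, idx[[nm]]] <<- PG[, idx[[nm]]] + val
  dh2 <- lapply(seq_len(n), function(j) matrix(0, W, ncol(trunks[[1]]$h2)))
  for (d in seq_len(D)) {
    for (spin in c("up", if (nd > 0) "down")) {
      b <- blocks[[d]][[spin]]
      hs <- heads[[d]][[spin]]
      nb <- if (spin == "up") nu else nd
      off <- if (spin == "up") 0 else nu
      V <- w[[paste0("V_", spin, "_", d)]]
      K <- nrow(V)
      dV <- matrix(0, W, K * ncol(V))
      dc <- matrix(0, W, K)
      dla <- matrix(0, W, K)
      for (j in seq_len(nb)) {
        # adjoint on phi_k(x_j): w_d * inv[k, j]
        Aj <- wd[, d] * vapply(seq_len(K), function(k) b$inv[[k]][, j],
                               numeric(W))
        Aj <- matrix(Aj, W, K)
        do_ <- Aj * hs[[j]]$env
        dc <- dc + do_
        dla <- dla + Aj * hs[[j]]$val * (-hs[[j]]$alpha[col(Aj)] * trunks[[off + j]]$r)
        # column-major packing matches as.numeric(V): element (k, h) sits
        # at position (h - 1) * K + k in the flat parameter vector
        for (h in seq_len(ncol(V)))
          dV[, (h - 1) * K + seq_len(K)] <-
            dV[, (h - 1) * K + seq_len(K)] +
            do_ * trunks[[off + j]]$h2[, h]
        dh2[[off + j]] <- dh2[[off + j]] + do_ %*% V
      }
      add(paste0("V_", spin, "_", d), dV)
      add(paste0("c_", spin, "_", d), dc)
      add(paste0("la_", spin, "_", d), dla)
    }
    add("cdet", {
      m <- matrix(0, W, D)
      m[, d] <- wd[, d] / w$cdet[d]
      m
    })
  }
  # trunk backprop, shared over electrons
  H1 <- length(w$b1); H2 <- length(w$b2); F_in <- ncol(trunks[[1]]$f)
  dW1 <- matrix(0, W, H1 * F_in); db1 <- matrix(0, W, H1)
  dW2 <- matrix(0, W, H2 * H1); db2 <- matrix(0, W, H2)
  for (j in seq_len(n)) {
    tr <- trunks[[j]]
    dz2 <- dh2[[j]] * tr$t2
    db2 <- db2 + dz2
    for (b in seq_len(H1))
      dW2[, (b - 1) * H2 + seq_len(H2)] <-
        dW2[, (b - 1) * H2 + seq_len(H2)] + dz2 * tr$h1[, b]
    dh1 <- dz2 %*% w$W2
    dz1 <- dh1 * tr$t1
    db1 <- db1 + dz1
    for (b in seq_len(F_in))
      dW1[, (b - 1) * H1 + seq_len(H1)] <-
        dW1[, (b - 1) * H1 + seq_len(H1)] + dz1 * tr$f[, b]
  }
  add("W1", dW1); add("b1", db1); add("W2", dW2); add("b2", db2)
  add("jb", jj$pgrad)
  out$param_grad <- PG
  out
}

#' Compact neural trial wavefunction for a single atom
#'
#' A two-hidden-layer tanh network applied per electron feeds `n_det`
#' determinants per spin channel through linear heads with trainable STO
#' envelopes `exp(-alpha_k r)`; the determinant sum is multiplied by a
#' cusp-correct electron-electron Pade Jastrow.  All free parameters
#' (trunk, heads, envelopes, determinant coefficients, Jastrow widths) are
#' exposed as one flat vector for the VMC optimizer.
#'
#' @param system a single-atom `fndmc_system`.
#' @param n_det number of determinants (default 2).
#' @param width hidden-layer width (default 16, capped at 32).
#' @param init_seed RNG seed for weight initialization.
#' @param theta optional flat parameter vector (overrides initialization).
#' @return a `fndmc_trial` with `param_grad` support.
#' @export
make_neural_trial <- function(system, n_det = 2, width = 16, init_seed = 1,
                              theta = NULL) {
  if (is.null(system$nuclear_positions) || length(system$nuclear_charges) != 1)
    stop("the neural trial supports single-atom systems")
  if (width > 32) stop("width is capped at 32")
  nu <- system$n_up; nd <- system$n_down
  Z <- system$nuclear_charges[1]
  shapes <- neural_shapes(4, width, width, nu, nd, n_det)
  lens <- vapply(shapes, prod, 0)
  ends <- cumsum(lens)
  idx <- stats::setNames(lapply(seq_along(lens), function(i)
    (ends[i] - lens[i] + 1):ends[i]), names(shapes))
  sysinfo <- list(n_up = nu, n_down = nd, D = n_det,
                  center = system$nuclear_positions[1, ],
                  shapes = shapes, idx = idx, n_params = sum(lens))
  if (is.null(theta)) {
    theta <- neural_flatten(neural_init(4, width, width, nu, nd, n_det, Z,
                                        init_seed), shapes)
  }
  build <- function(p) {
    w <- neural_unflatten(as.numeric(p), shapes)
    new_trial(
      "neural", system,
      stats::setNames(as.numeric(p), paste0("theta", seq_along(p))),
      logpsi = function(X)
        neural_eval(as_walker_matrix(X), sysinfo, w, want = "log")[c("sign", "log")],
      grad = function(X)
        neural_eval(as_walker_matrix(X), sysinfo, w, want = "derivs")$grad,
      lap = function(X)
        neural_eval(as_walker_matrix(X), sysinfo, w, want = "derivs")$lap,
      param_grad = function(X)
        neural_eval(as_walker_matrix(X), sysinfo, w, want = "pgrad")$param_grad,
      nodeless = (nu <= 1 && nd <= 1),
      exact_node = (nu <= 1 && nd <= 1),
      rebuild = build
    )
  }
  tr <- build(theta)
  tr$full <- function(X) {
    w <- neural_unflatten(as.numeric(tr$params), shapes)
    neural_eval(as_walker_matrix(X), sysinfo, w, want = "derivs")
  }
  tr
}

#' Evaluate sign, log-magnitude, gradient and Laplacian in one pass
#'
#' Uses the trial's fused evaluation path when available (the neural
#' ansatz), otherwise falls back to the individual contract functions.
#' @param trial a `fndmc_trial`.
#' @param X walker matrix.
#' @return list with `sign`, `log`, `grad`, `lap`.
#' @export
trial_full_eval <- function(trial, X) {
  X <- as_walker_matrix(X)
  if (!is.null(trial$full)) return(trial$full(X))
  lp <- trial$logpsi(X)
  list(sign = lp$sign, log = lp$log, grad = trial$grad(X), lap = trial$lap(X))
}
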