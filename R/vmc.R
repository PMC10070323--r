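# Variational Monte Carlo: Metropolis sampling of psi_T^2, energy
# inference, and a plain stochastic-gradient optimizer used to generate
# training trajectories for the VMC-DMC extrapolation scheme.

#' VMC run parameters
#'
#' @param n_walkers walkers per batch.
#' @param n_steps Metropolis sweeps.
#' @param step_size Gaussian proposal width (bohr).
#' @param move_mode `"all"` (all-electron moves) or `"single"`
#'   (one randomly chosen electron per sweep).  Default: single-electron
#'   moves above 4 electrons (acceptance scaling), all-electron below.
#' @param burn_in_fraction fraction of sweeps discarded before production
#'   (default 0.1, mirroring the DMC equilibration convention).
#' @param seed RNG seed.
#' @return list of validated parameters.
#' @export
vmc_params <- function(n_walkers = 500, n_steps = 500, step_size = 0.5,
                       move_mode = NULL, burn_in_fraction = 0.1, seed = 1) {
  stopifnot(n_walkers >= 1, n_steps >= 1, step_size > 0,
            burn_in_fraction >= 0, burn_in_fraction < 1)
  list(n_walkers = as.integer(n_walkers), n_steps = as.integer(n_steps),
       step_size = step_size, move_mode = move_mode,
       burn_in_fraction = burn_in_fraction, seed = as.integer(seed))
}

# one Metropolis sweep in place; returns updated state and acceptance count
.vmc_sweep <- function(trial, X, lp, step_size, move_mode, d) {
  W <- nrow(X)
  nc <- ncol(X)
  if (move_mode == "all") {
    Xp <- X + matrix(stats::rnorm(W * nc, sd = step_size), W, nc)
  } else {
    n <- nc %/% d
    Xp <- X
    pick <- sample.int(n, W, replace = TRUE)
    for (i in unique(pick)) {
      rows <- which(pick == i)
      cols <- d * (i - 1) + seq_len(d)
      Xp[rows, cols] <- Xp[rows, cols] +
        matrix(stats::rnorm(length(rows) * d, sd = step_size), length(rows), d)
    }
  }
  lpp <- trial$logpsi(Xp)
  logA <- 2 * (lpp$log - lp$log)
  acc <- log(stats::runif(W)) < logA
  acc[!is.finite(lpp$log)] <- FALSE
  X[acc, ] <- Xp[acc, , drop = FALSE]
  lp$log[acc] <- lpp$log[acc]
  lp$sign[acc] <- lpp$sign[acc]
  list(X = X, lp = lp, n_acc = sum(acc))
}

#' Metropolis sampling of the trial density psi_T^2
#'
#' Gaussian proposals of the stated step size; acceptance ratio
#' `exp(2 (log|psi(x')| - log|psi(x)|))`.  Walkers whose starting point has
#' zero magnitude are redrawn.
#'
#' @param trial a `fndmc_trial`.
#' @param system owning system (defaults to `trial$system`).
#' @param params a [vmc_params()] list.
#' @param record `"ensembles"` keeps every `thin`-th walker ensemble,
#'   `"final"` only the last.
#' @param thin keep every `thin`-th ensemble when recording.
#' @return list with `ensembles` (list of walker matrices), `final` (last
#'   ensemble), `acceptance` (overall acceptance rate).
#' @export
metropolis_sample <- function(trial, system = trial$system, params = vmc_params(),
                              record = c("final", "ensembles"), thin = 10) {
  record <- match.arg(record)
  X <- init_walkers(system, params$n_walkers, seed = params$seed)
  d <- system$d
  move_mode <- params$move_mode %||% if (n_electrons(system) > 4) "single" else "all"
  lp <- trial$logpsi(X)
  for (tries in 1:50) {
    bad <- !is.finite(lp$log)
    if (!any(bad)) break
    X[bad, ] <- random_configs(system, sum(bad))
    lp <- trial$logpsi(X)
  }
  ensembles <- list()
  n_acc <- 0
  for (s in seq_len(params$n_steps)) {
    sw <- .vmc_sweep(trial, X, lp, params$step_size, move_mode, d)
    X <- sw$X; lp <- sw$lp; n_acc <- n_acc + sw$n_acc
    if (record == "ensembles" && s %% thin == 0)
      ensembles[[length(ensembles) + 1]] <- X
  }
  list(ensembles = ensembles, final = X,
       acceptance = n_acc / (params$n_steps * params$n_walkers))
}

#' Variational energy of a trial wavefunction
#'
#' Runs Metropolis sampling, discards the burn-in fraction, records the
#' batch-mean local energy per sweep, and returns the reblocked mean and
#' standard error.  Sweeps on which a walker's local energy is not finite
#' (essentially coincident particles) have that walker excluded from the
#' batch mean; occurrences are counted in `n_singular`.
#'
#' @param trial a `fndmc_trial`.
#' @param system owning system (defaults to `trial$system`).
#' @param params a [vmc_params()] list.
#' @return a `fndmc_energy` (see [reblock()]) with extra fields
#'   `acceptance` and `n_singular`.
#' @export
vmc_energy <- function(trial, system = trial$system, params = vmc_params()) {
  X <- init_walkers(system, params$n_walkers, seed = params$seed)
  d <- system$d
  move_mode <- params$move_mode %||% if (n_electrons(system) > 4) "single" else "all"
  lp <- trial$logpsi(X)
  for (tries in 1:50) {
    bad <- !is.finite(lp$log)
    if (!any(bad)) break
    X[bad, ] <- random_configs(system, sum(bad))
    lp <- trial$logpsi(X)
  }
  burn <- floor(params$burn_in_fraction * params$n_steps)
  series <- numeric(params$n_steps - burn)
  n_acc <- 0; n_singular <- 0
  for (s in seq_len(params$n_steps)) {
    sw <- .vmc_sweep(trial, X, lp, params$step_size, move_mode, d)
    X <- sw$X; lp <- sw$lp; n_acc <- n_acc + sw$n_acc
    if (s > burn) {
      el <- batch_local_energy(trial, X)
      ok <- is.finite(el)
      n_singular <- n_singular + sum(!ok)
      series[s - burn] <- mean(el[ok])
    }
  }
  est <- reblock(series)
  est$acceptance <- n_acc / (params$n_steps * params$n_walkers)
  est$n_singular <- n_singular
  est
}

# local energy without the singularity stop (non-finite values allowed,
# handled by callers)
#' @keywords internal
batch_local_energy <- function(trial, X) {
  X <- as_walker_matrix(X)
  sys <- trial$system
  fe <- trial_full_eval(trial, X)
  n <- n_electrons(sys)
  d <- sys$d
  g2 <- matrix(0, nrow(X), n)
  for (i in seq_len(n))
    g2[, i] <- rowSums(fe$grad[, d * (i - 1) + seq_len(d), drop = FALSE]^2)
  -0.5 * rowSums(fe$lap + g2) + potential_energy(sys, X)
}

#' Variational optimization of a parametrized trial
#'
#' Plain stochastic gradient descent on the variational energy.  The
#' gradient estimator is `2 Cov(E_L, d log|psi| / d theta)` over the
#' sampled batch; local energies are winsorized at the batch median plus or
#' minus 5 mean absolute deviations for gradient stability (the energy
#' record itself is unclipped).  Parameter derivatives come from the
#' trial's `param_grad` or, when absent, central finite differences.
#'
#' @param trial a `fndmc_trial` with at least one free parameter.
#' @param system owning system (defaults to `trial$system`).
#' @param params a [vmc_params()] list; `n_steps` is the number of
#'   Metropolis sweeps between parameter updates (default 10 works well).
#' @param n_iters number of SGD iterations.
#' @param learning_rate SGD step size.
#' @param checkpoint_every record parameters every this many iterations
#'   (the final iteration is always recorded).
#' @param verbose print progress every 50 iterations.
#' @return list with `trial` (optimized), `trajectory` (data frame: iter,
#'   energy, stderr, acceptance), `checkpoints` (list of iter/params),
#'   `diverged` flag.
#' @export
optimize_trial <- function(trial, system = trial$system, params = vmc_params(n_steps = 10),
                           n_iters = 200, learning_rate = 0.05,
                           checkpoint_every = 10, verbose = FALSE) {
  if (!length(trial$params)) stop("trial has no free parameters")
  set.seed(params$seed)
  X <- init_walkers(system, params$n_walkers,
                    seed = params$seed + 1L)
  d <- system$d
  move_mode <- params$move_mode %||% if (n_electrons(system) > 4) "single" else "all"
  lp <- trial$logpsi(X)
  for (tries in 1:50) {
    bad <- !is.finite(lp$log)
    if (!any(bad)) break
    X[bad, ] <- random_configs(system, sum(bad))
    lp <- trial$logpsi(X)
  }
  traj <- data.frame(iter = integer(), energy = numeric(), stderr = numeric(),
                     acceptance = numeric())
  checkpoints <- list()
  theta <- as.numeric(trial$params)
  diverged <- FALSE
  for (it in seq_len(n_iters)) {
    n_acc <- 0
    for (s in seq_len(params$n_steps)) {
      sw <- .vmc_sweep(trial, X, lp, params$step_size, move_mode, d)
      X <- sw$X; lp <- sw$lp; n_acc <- n_acc + sw$n_acc
    }
    el <- batch_local_energy(trial, X)
    ok <- is.finite(el)
    if (!any(ok)) { diverged <- TRUE; break }
    elv <- el[ok]
    med <- stats::median(elv)
    mad5 <- 5 * mean(abs(elv - med))
    elc <- pmin(pmax(el, med - mad5), med + mad5)
    g <- if (!is.null(trial$param_grad)) trial$param_grad(X)
         else fd_param_grad(trial, X)
    g <- matrix(g, nrow(X))
    grad <- 2 * (colMeans(elc[ok] * g[ok, , drop = FALSE]) -
                 mean(elc[ok]) * colMeans(g[ok, , drop = FALSE]))
    if (anyNA(grad) || any(!is.finite(grad))) { diverged <- TRUE; break }
    energy <- mean(elv)
    if (!is.finite(energy)) { diverged <- TRUE; break }
    traj <- rbind(traj, data.frame(
      iter = it, energy = energy,
      stderr = stats::sd(elv) / sqrt(length(elv)),
      acceptance = n_acc / (params$n_steps * params$n_walkers)))
    if (learning_rate != 0) {
      theta_new <- theta - learning_rate * grad
      trial_new <- try(set_trial_params(trial, theta_new), silent = TRUE)
      if (inherits(trial_new, "try-error")) { diverged <- TRUE; break }
      theta <- theta_new
      trial <- trial_new
      lp <- trial$logpsi(X)
    }
    if (it %% checkpoint_every == 0 || it == n_iters)
      checkpoints[[length(checkpoints) + 1]] <- list(iter = it, params = theta)
    if (verbose && it %% 50 == 0)
      message(sprintf("iter %d  E = %.6f", it, energy))
  }
  list(trial = trial, trajectory = traj, checkpoints = checkpoints,
       diverged = diverged)
}

# central finite-difference parameter gradient of log|psi|
#' @keywords internal
fd_param_grad <- function(trial, X, h = 1e-5) {
  X <- as_walker_matrix(X)
  theta <- as.numeric(trial$params)
  G <- matrix(0, nrow(X), length(theta))
  for (p in seq_along(theta)) {
    tp <- theta; tm <- theta
    tp[p] <- tp[p] + h; tm[p] <- tm[p] - h
    lp <- set_trial_params(trial, tp)$logpsi(X)$log
    lm_ <- set_trial_params(trial, tm)$logpsi(X)$log
    G[, p] <- (lp - lm_) / (2 * h)
  }
  G
}
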