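# Importance-sampled fixed-node diffusion Monte Carlo.
#
# One iteration: drift-diffuse every walker (rejecting node crossings and
# applying the importance-sampled Green's-function Metropolis test), update
# weights with the clipped mixed local energy, branch heavy walkers while
# merging the two lightest (keeping the population exactly constant), then
# adjust the trial-energy offset by logarithmic population feedback.

#' DMC run parameters
#'
#' @param tau imaginary-time step (Ha^-1).
#' @param n_steps number of DMC iterations.
#' @param n_walkers fixed population size.
#' @param target_weight population-control setpoint (default `n_walkers`).
#' @param et_damping trial-energy feedback time constant (Ha^-1); default
#'   `10 * tau`.
#' @param branch_threshold walkers heavier than this split in two (> 1).
#' @param merge_threshold nominal light-walker scale (in (0,1)); merging is
#'   tied to branching (the two lightest walkers merge whenever a branch
#'   occurs), so this is diagnostic only.
#' @param clip_alpha local-energy clipping constant: energies entering the
#'   weights are limited to the running estimate plus or minus
#'   `clip_alpha / sqrt(tau)`.  Default `0.2 * sqrt(n_electrons)` (set at
#'   run time when `NULL`).
#' @param vmc_equil_steps Metropolis pre-equilibration sweeps before the
#'   first DMC iteration.
#' @param seed RNG seed.
#' @return validated parameter list.
#' @export
dmc_params <- function(tau = 0.01, n_steps = 1000, n_walkers = 500,
                       target_weight = NULL, et_damping = NULL,
                       branch_threshold = 2, merge_threshold = 0.3,
                       clip_alpha = NULL, vmc_equil_steps = 100, seed = 1) {
  stopifnot(tau > 0, n_steps >= 1, n_walkers >= 1,
            branch_threshold > 1, merge_threshold > 0, merge_threshold < 1)
  list(tau = tau, n_steps = as.integer(n_steps),
       n_walkers = as.integer(n_walkers),
       target_weight = target_weight %||% n_walkers,
       et_damping = et_damping %||% (10 * tau),
       branch_threshold = branch_threshold,
       merge_threshold = merge_threshold,
       clip_alpha = clip_alpha, vmc_equil_steps = as.integer(vmc_equil_steps),
       seed = as.integer(seed))
}

# per-electron drift limiting factor (Umrigar-style):
# vbar = v (-1 + sqrt(1 + 2 |v|^2 tau)) / (|v|^2 tau), -> v as |v|^2 tau -> 0
#' @keywords internal
limit_drift_matrix <- function(G, tau, d) {
  n <- ncol(G) %/% d
  for (i in seq_len(n)) {
    cols <- d * (i - 1) + seq_len(d)
    v2 <- rowSums(G[, cols, drop = FALSE]^2)
    a <- v2 * tau
    fac <- ifelse(a < 1e-12, 1 - a / 2, (-1 + sqrt(1 + 2 * a)) / a)
    G[, cols] <- G[, cols] * fac
  }
  G
}

#' Limited drift velocity
#'
#' The drift `v = grad log|psi_T|` is limited per electron by
#' `vbar = v (-1 + sqrt(1 + 2 |v|^2 tau)) / (|v|^2 tau)`, which reduces the
#' time-step error from divergent drift near nodes and nuclei: `|vbar| <=
#' |v|`, `vbar -> v` as `|v|^2 tau -> 0`, and the direction is preserved.
#'
#' @param trial a `fndmc_trial`.
#' @param X configuration (vector) or walker matrix.
#' @param tau time step (Ha^-1).
#' @return matrix of limited drift velocities, same shape as `X`.
#' @export
limited_drift <- function(trial, X, tau) {
  stopifnot(tau > 0)
  X <- as_walker_matrix(X)
  limit_drift_matrix(trial$grad(X), tau, trial$system$d)
}

#' Initialize a DMC state
#'
#' Draws walkers around the nuclei, equilibrates them with plain Metropolis
#' sweeps towards psi_T^2, and caches the trial evaluation and local
#' energies.  Uses the current RNG stream ([run_dmc()] seeds it).
#'
#' @param trial a `fndmc_trial`.
#' @param system owning system.
#' @param params a [dmc_params()] list.
#' @return a `fndmc_dmc_state`.
#' @export
dmc_init <- function(trial, system = trial$system, params = dmc_params()) {
  X <- init_walkers(system, params$n_walkers, seed = params$seed)
  d <- system$d
  lp <- trial$logpsi(X)
  for (tries in 1:50) {
    bad <- !is.finite(lp$log)
    if (!any(bad)) break
    X[bad, ] <- random_configs(system, sum(bad))
    lp <- trial$logpsi(X)
  }
  move_mode <- if (n_electrons(system) > 4) "single" else "all"
  for (s in seq_len(params$vmc_equil_steps)) {
    sw <- .vmc_sweep(trial, X, lp, 0.5, move_mode, d)
    X <- sw$X; lp <- sw$lp
  }
  fe <- trial_full_eval(trial, X)
  eloc <- eloc_from_eval(trial, system, X, fe)
  bad <- !is.finite(eloc)
  if (any(bad)) {
    src <- sample(which(!bad), sum(bad), replace = TRUE)
    X[bad, ] <- X[src, , drop = FALSE]
    fe <- trial_full_eval(trial, X)
    eloc <- eloc_from_eval(trial, system, X, fe)
  }
  e0 <- mean(eloc)
  structure(list(
    X = X, w = rep(1, params$n_walkers),
    sign = fe$sign, logpsi = fe$log, grad = fe$grad, eloc = eloc,
    E_T = e0, E_best = e0, tau_eff = params$tau, iteration = 0L,
    energy_series = numeric(256), weight_series = numeric(256),
    et_series = numeric(256), e_series_sum = 0,
    counters = c(n_acc = 0, n_prop = 0, n_cross = 0, n_branch = 0,
                 n_clip = 0, n_eval = 0, n_resampled = 0),
    tau_eff_sum = 0
  ), class = "fndmc_dmc_state")
}

#' @keywords internal
eloc_from_eval <- function(trial, system, X, fe) {
  n <- n_electrons(system)
  d <- system$d
  g2 <- matrix(0, nrow(X), n)
  for (i in seq_len(n))
    g2[, i] <- rowSums(fe$grad[, d * (i - 1) + seq_len(d), drop = FALSE]^2)
  -0.5 * rowSums(fe$lap + g2) + potential_energy(system, X)
}

#' One DMC iteration
#'
#' Proposes `x' = x + vbar tau + chi sqrt(tau)` per walker, rejects any
#' proposal whose trial sign differs from the current one (the fixed-node
#' constraint), applies the importance-sampled Green's-function Metropolis
#' test, rescales the effective time step by the accepted-to-proposed
#' mean-squared-displacement ratio, updates the weights with the
#' symmetrized clipped local energy relative to the trial energy offset,
#' appends the weighted mean clipped local energy to the energy series,
#' enforces the constant-population branch-merge rule, and adjusts the
#' trial energy by logarithmic population feedback.
#'
#' @param trial a `fndmc_trial`.
#' @param system owning system.
#' @param state a `fndmc_dmc_state`.
#' @param params a [dmc_params()] list.
#' @return the advanced state.
#' @export
dmc_step <- function(trial, system = trial$system, state, params) {
  tau <- params$tau
  d <- system$d
  W <- nrow(state$X)
  nc <- ncol(state$X)
  clip_alpha <- params$clip_alpha %||% (0.2 * sqrt(n_electrons(system)))

  vbar <- limit_drift_matrix(state$grad, tau, d)
  noise <- matrix(stats::rnorm(W * nc, sd = sqrt(tau)), W, nc)
  Xp <- state$X + vbar * tau + noise
  fe_p <- trial_full_eval(trial, Xp)
  cross <- (fe_p$sign != state$sign) | !is.finite(fe_p$log)
  vbar_p <- limit_drift_matrix(fe_p$grad, tau, d)
  vbar_p[!is.finite(vbar_p)] <- 0
  # log G(x -> x') = -|x' - x - vbar(x) tau|^2 / (2 tau)
  log_g_fwd <- -rowSums(noise^2) / (2 * tau)
  log_g_rev <- -rowSums((state$X - Xp - vbar_p * tau)^2) / (2 * tau)
  logA <- 2 * (fe_p$log - state$logpsi) + log_g_rev - log_g_fwd
  logA[cross] <- -Inf
  acc <- log(stats::runif(W)) < logA

  disp2 <- rowSums((Xp - state$X)^2)
  sum_prop <- sum(disp2)
  tau_eff <- if (sum_prop > 0) tau * sum(disp2[acc]) / sum_prop else tau

  eloc_old <- state$eloc
  if (any(acc)) {
    state$X[acc, ] <- Xp[acc, , drop = FALSE]
    state$sign[acc] <- fe_p$sign[acc]
    state$logpsi[acc] <- fe_p$log[acc]
    state$grad[acc, ] <- fe_p$grad[acc, , drop = FALSE]
    eloc_p <- eloc_from_eval(trial, system, Xp, fe_p)
    state$eloc[acc] <- eloc_p[acc]
  }
  # a non-finite local energy marks a pathological walker: replace it with a
  # copy of a healthy one (weight kept) and count the event
  bad <- !is.finite(state$eloc)
  if (any(bad)) {
    if (all(bad)) stop("all walkers pathological (non-finite local energy)")
    src <- sample(which(!bad), sum(bad), replace = TRUE)
    state$X[bad, ] <- state$X[src, , drop = FALSE]
    state$sign[bad] <- state$sign[src]
    state$logpsi[bad] <- state$logpsi[src]
    state$grad[bad, ] <- state$grad[src, , drop = FALSE]
    state$eloc[bad] <- state$eloc[src]
    eloc_old[bad] <- state$eloc[bad]
    state$counters["n_resampled"] <- state$counters["n_resampled"] + sum(bad)
  }

  cw <- clip_alpha / sqrt(tau)
  clip <- function(e) pmin(pmax(e, state$E_best - cw), state$E_best + cw)
  e_new <- clip(state$eloc)
  e_old <- clip(eloc_old)
  state$counters["n_clip"] <- state$counters["n_clip"] +
    sum(e_new != state$eloc)
  state$counters["n_eval"] <- state$counters["n_eval"] + W
  state$w <- state$w * exp(-tau_eff * (0.5 * (e_new + e_old) - state$E_T))

  e_mix <- sum(state$w * e_new) / sum(state$w)
  state$iteration <- state$iteration + 1L
  if (state$iteration > length(state$energy_series)) {   # amortized growth
    grow <- function(v) c(v, numeric(length(v)))
    state$energy_series <- grow(state$energy_series)
    state$weight_series <- grow(state$weight_series)
    state$et_series <- grow(state$et_series)
  }
  state$energy_series[state$iteration] <- e_mix
  state$weight_series[state$iteration] <- sum(state$w)
  state$e_series_sum <- state$e_series_sum + e_mix
  state$tau_eff <- tau_eff
  state$tau_eff_sum <- state$tau_eff_sum + tau_eff
  state$counters["n_acc"] <- state$counters["n_acc"] + sum(acc)
  state$counters["n_prop"] <- state$counters["n_prop"] + W
  state$counters["n_cross"] <- state$counters["n_cross"] + sum(cross)

  ens <- list(X = state$X, w = state$w, sign = state$sign,
              logpsi = state$logpsi, grad = state$grad, eloc = state$eloc)
  bm <- branch_merge(ens, params)
  state$X <- bm$ensemble$X; state$w <- bm$ensemble$w
  state$sign <- bm$ensemble$sign; state$logpsi <- bm$ensemble$logpsi
  state$grad <- bm$ensemble$grad; state$eloc <- bm$ensemble$eloc
  state$counters["n_branch"] <- state$counters["n_branch"] + bm$n_branch

  # running mixed estimate feeds both the clip window and the E_T feedback
  state$E_best <- state$e_series_sum / state$iteration
  state$E_T <- update_trial_energy(state, params)
  state$et_series[state$iteration] <- state$E_T
  state
}

#' Constant-population branch-merge
#'
#' Every walker whose weight exceeds `branch_threshold` splits into two
#' walkers of half weight; for each split, the two lightest remaining
#' walkers merge into one, positioned at one of the two chosen with
#' probability proportional to weight and carrying the summed weight.  No
#' merging happens without a branch, the population never changes, and the
#' total weight is conserved exactly.
#'
#' @param ensemble list with at least `X` (walker matrix) and `w` (positive
#'   weights); any further same-length fields (cached signs, log
#'   magnitudes, gradients, local energies) are carried along.
#' @param params a [dmc_params()] list (only `branch_threshold` is used).
#' @return list with `ensemble` (same shape) and `n_branch`.
#' @export
branch_merge <- function(ensemble, params) {
  w <- ensemble$w
  N <- length(w)
  fields <- setdiff(names(ensemble), "w")
  copy_rows <- function(from, to) {
    for (f in fields) {
      if (is.matrix(ensemble[[f]]))
        ensemble[[f]][to, ] <<- ensemble[[f]][from, , drop = FALSE]
      else ensemble[[f]][to] <<- ensemble[[f]][from]
    }
  }
  n_branch <- 0L
  heavy <- which(w > params$branch_threshold)   # one pass per iteration:
  if (length(heavy)) {                          # walkers born of a merge wait
    if (N < 3) stop("cannot branch with fewer than 3 walkers")
    heavy <- heavy[order(w[heavy], decreasing = TRUE)]
    light <- setdiff(order(w), heavy)        # ascending weight, non-branching
    n_do <- min(length(heavy), length(light) %/% 2)
    if (n_do == 0) stop("cannot branch: not enough light walkers to merge")
    heavy <- heavy[seq_len(n_do)]
    j1 <- light[2 * seq_len(n_do) - 1]
    j2 <- light[2 * seq_len(n_do)]
    # merged walker sits at one of the pair, chosen proportionally to weight
    take1 <- stats::runif(n_do) < w[j1] / (w[j1] + w[j2])
    surv <- ifelse(take1, j1, j2)
    loser <- ifelse(take1, j2, j1)
    merged_w <- w[j1] + w[j2]
    w[surv] <- merged_w
    w[heavy] <- w[heavy] / 2
    copy_rows(heavy, loser)                  # freed slots take the branch copies
    w[loser] <- w[heavy]
    n_branch <- n_branch + n_do
  }
  ensemble$w <- w
  list(ensemble = ensemble, n_branch = n_branch)
}

#' Trial-energy population feedback
#'
#' `E_T = E_best - log(W / target_weight) / et_damping` with `W` the total
#' weight: negative feedback that pins the population near the setpoint
#' while the offset tracks the running mixed estimate.
#'
#' @param state a `fndmc_dmc_state` (uses `E_best` and the weights).
#' @param params a [dmc_params()] list.
#' @return the new trial energy (Hartree).
#' @export
update_trial_energy <- function(state, params) {
  W <- sum(state$w)
  stopifnot(W > 0)
  state$E_best - log(W / params$target_weight) / params$et_damping
}

#' Run fixed-node diffusion Monte Carlo
#'
#' Initializes (or resumes) a walker population, iterates [dmc_step()],
#' discards the first 10% of iterations as equilibration and returns the
#' weight-averaged mixed estimator over the production phase with a
#' reblocked standard error, plus time series and diagnostics.
#'
#' @param trial a `fndmc_trial`.
#' @param system owning system (defaults to `trial$system`).
#' @param params a [dmc_params()] list.
#' @param resume_state optionally a state from a previous (shorter) run;
#'   `n_steps` then counts additional iterations and the RNG stream
#'   continues from the saved one.
#' @return an object of class `fndmc_dmc`: `energy` (a `fndmc_energy`;
#'   mean is the total-weight-weighted production average),
#'   `energy_series`, `et_series`, `weight_series`, `state` (final),
#'   `diagnostics` (acceptance rate, mean `tau_eff/tau`, branch count,
#'   clip-activation fraction, cross-node rejection fraction, resampled
#'   walkers).
#' @export
run_dmc <- function(trial, system = trial$system, params = dmc_params(),
                    resume_state = NULL) {
  if (is.null(resume_state)) {
    set.seed(params$seed)
    state <- dmc_init(trial, system, params)
  } else {
    state <- resume_state
    if (!is.null(attr(state, "rng_state")))
      assign(".Random.seed", attr(state, "rng_state"), envir = globalenv())
  }
  for (s in seq_len(params$n_steps)) state <- dmc_step(trial, system, state, params)
  attr(state, "rng_state") <- get(".Random.seed", envir = globalenv())
  n_tot <- state$iteration
  state$energy_series <- state$energy_series[seq_len(n_tot)]
  state$weight_series <- state$weight_series[seq_len(n_tot)]
  state$et_series <- state$et_series[seq_len(n_tot)]
  equil <- floor(0.1 * n_tot)
  prod_e <- state$energy_series[(equil + 1):n_tot]
  prod_w <- state$weight_series[(equil + 1):n_tot]
  est <- reblock(prod_e)
  est$mean <- sum(prod_w * prod_e) / sum(prod_w)
  cnt <- state$counters
  structure(list(
    energy = est,
    energy_series = state$energy_series,
    et_series = state$et_series,
    weight_series = state$weight_series,
    state = state,
    n_equilibration = equil,
    diagnostics = list(
      acceptance = unname(cnt["n_acc"] / cnt["n_prop"]),
      cross_fraction = unname(cnt["n_cross"] / cnt["n_prop"]),
      tau_eff_ratio = state$tau_eff_sum / (state$iteration * params$tau),
      n_branch = unname(cnt["n_branch"]),
      clip_fraction = unname(cnt["n_clip"] / cnt["n_eval"]),
      n_resampled = unname(cnt["n_resampled"])
    )
  ), class = "fndmc_dmc")
}

#' @export
print.fndmc_dmc <- function(x, ...) {
  cat(sprintf("FN-DMC: E = %.6f +/- %.6f Ha  (%d steps, %d equilibration)\n",
              x$energy$mean, x$energy$stderr,
              length(x$energy_series), x$n_equilibration))
  cat(sprintf("  acceptance %.3f | tau_eff/tau %.4f | branches %d | clip %.4f\n",
              x$diagnostics$acceptance, x$diagnostics$tau_eff_ratio,
              x$diagnostics$n_branch, x$diagnostics$clip_fraction))
  invisible(x)
}

#' Linear zero-time-step extrapolation of DMC energies
#'
#' Runs FN-DMC at several time steps and extrapolates the energy linearly
#' to `tau -> 0` by weighted least squares.
#'
#' @param trial a `fndmc_trial`.
#' @param system owning system.
#' @param taus vector of time steps (Ha^-1).
#' @param params base [dmc_params()]; `tau` is overridden per run, and
#'   `n_steps` is scaled inversely with `tau` relative to `params$tau` so
#'   each run covers the same total imaginary time.
#' @return list: `energy` (extrapolated, Hartree), `stderr` (fit), `runs`
#'   (per-tau results), `fit` (the `lm` object).
#' @export
dmc_tau_extrapolation <- function(trial, system = trial$system, taus,
                                  params = dmc_params()) {
  runs <- lapply(taus, function(tt) {
    p <- params
    p$tau <- tt
    p$n_steps <- as.integer(ceiling(params$n_steps * params$tau / tt))
    p$et_damping <- 10 * tt
    run_dmc(trial, system, p)
  })
  e <- vapply(runs, function(r) r$energy$mean, 0)
  se <- vapply(runs, function(r) r$energy$stderr, 0)
  fit <- stats::lm(e ~ taus, weights = 1 / pmax(se, 1e-12)^2)
  sm <- summary(fit)
  list(energy = unname(stats::coef(fit)[1]),
       stderr = sm$coefficients[1, 2],
       table = data.frame(tau = taus, energy = e, stderr = se),
       runs = runs, fit = fit)
}
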