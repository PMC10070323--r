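# Reblocking error analysis and the VMC-DMC linear-relation extrapolation.

#' Reblocked mean and standard error of a correlated series
#'
#' Flyvbjerg-Petersen successive pairwise blocking: at each transform the
#' series is replaced by the means of consecutive pairs, and the naive
#' standard error of the blocked series is recorded.  The plateau is the
#' first block level at which the standard-error estimate changes by less
#' than 5% over two successive levels; if no level qualifies, the deepest
#' usable level is taken.  The reported standard error is never below the
#' naive (unblocked) one, since autocorrelation can only inflate it.
#'
#' @param series numeric vector (length >= 8).
#' @return an object of class `fndmc_energy` with fields `mean` (the exact
#'   arithmetic mean), `stderr`, `n_samples`, `block_curve` (data frame:
#'   level, block_size, n_blocks, stderr) and `plateau_index`.
#' @export
reblock <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 8) stop("reblock requires a series of length >= 8")
  if (anyNA(series)) stop("reblock: series contains NA")
  m <- mean(series)
  x <- series
  lev <- 0L
  curve <- data.frame(level = integer(), block_size = integer(),
                      n_blocks = integer(), stderr = numeric())
  while (length(x) >= 2) {
    nb <- length(x)
    se <- stats::sd(x) / sqrt(nb)
    curve <- rbind(curve, data.frame(level = lev, block_size = 2L^lev,
                                     n_blocks = nb, stderr = se))
    if (length(x) < 4) break
    n2 <- length(x) %/% 2
    x <- (x[2 * seq_len(n2) - 1] + x[2 * seq_len(n2)]) / 2
    lev <- lev + 1L
  }
  nl <- nrow(curve)
  # fallback: deepest level whose stderr estimate is itself usable
  plateau <- max(c(1, which(curve$n_blocks >= 8)))
  if (nl >= 3) {
    for (l in seq_len(nl - 2)) {
      d1 <- abs(curve$stderr[l + 1] - curve$stderr[l]) /
        max(curve$stderr[l], .Machine$double.xmin)
      d2 <- abs(curve$stderr[l + 2] - curve$stderr[l + 1]) /
        max(curve$stderr[l + 1], .Machine$double.xmin)
      if (d1 < 0.05 && d2 < 0.05) { plateau <- l; break }
    }
  }
  se <- max(curve$stderr[plateau], curve$stderr[1])
  structure(list(mean = m, stderr = se, n_samples = length(series),
                 block_curve = curve, plateau_index = plateau),
            class = "fndmc_energy")
}

#' @export
print.fndmc_energy <- function(x, ...) {
  cat(sprintf("energy %.6f +/- %.6f Ha  (n = %d, block level %d)\n",
              x$mean, x$stderr, x$n_samples,
              x$block_curve$level[x$plateau_index]))
  invisible(x)
}

#' Build a VMC/DMC energy trajectory table
#'
#' One row per VMC training step `k` at which a VMC and a DMC energy were
#' evaluated with the then-current trial wavefunction.
#'
#' @param k strictly increasing integer training steps.
#' @param E_VMC,E_DMC energies (Hartree).
#' @param E_VMC_err,E_DMC_err standard errors (optional).
#' @return data frame of class `fndmc_trajectory`.
#' @export
energy_trajectory <- function(k, E_VMC, E_DMC, E_VMC_err = NA_real_,
                              E_DMC_err = NA_real_) {
  if (is.unsorted(k, strictly = TRUE)) stop("k must be strictly increasing")
  structure(data.frame(k = k, E_VMC = E_VMC, E_VMC_err = E_VMC_err,
                       E_DMC = E_DMC, E_DMC_err = E_DMC_err),
            class = c("fndmc_trajectory", "data.frame"))
}

#' Fit the linear relation between VMC and DMC energies along training
#'
#' Along a variational optimization, the DMC energy relative to its final
#' value tends to be linear in the VMC-DMC gap:
#' `E_DMC(k) - E_final = w (E_VMC(k) - E_DMC(k)) + b`, with `E_final` the
#' DMC energy at the last available training step.  This fits `w` and `b`
#' by least squares (unweighted by default; weights `1/err^2` when
#' `weighted` and DMC standard errors are available).
#'
#' @param traj an [energy_trajectory()] (>= 3 rows).
#' @param weighted use inverse-variance weights from `E_DMC_err`.
#' @return an object of class `fndmc_extrap_fit`: `w` (slope), `b`
#'   (intercept, Hartree), `E_final`, `w_stderr`, `residuals`, `r_squared`,
#'   and the `fitted` trajectory.
#' @export
fit_linear_relation <- function(traj, weighted = FALSE) {
  if (nrow(traj) < 3) stop("need at least 3 trajectory points")
  E_final <- traj$E_DMC[nrow(traj)]
  x <- traj$E_VMC - traj$E_DMC
  y <- traj$E_DMC - E_final
  if (diff(range(x)) < 1e-14)
    stop("degenerate predictor: all E_VMC - E_DMC gaps are equal")
  wts <- NULL
  if (weighted && all(is.finite(traj$E_DMC_err)) && all(traj$E_DMC_err > 0))
    wts <- 1 / traj$E_DMC_err^2
  fit <- if (is.null(wts)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = wts)
  sm <- summary(fit)
  structure(list(
    w = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
    E_final = E_final,
    w_stderr = sm$coefficients[2, 2],
    residuals = stats::residuals(fit),
    r_squared = sm$r.squared,
    fitted = data.frame(k = traj$k, gap = x, dE = y,
                        dE_fit = stats::fitted(fit))
  ), class = "fndmc_extrap_fit")
}

#' @export
print.fndmc_extrap_fit <- function(x, ...) {
  cat(sprintf("VMC-DMC linear fit: w = %.4f +/- %.4f, b = %.6f Ha, R^2 = %.4f\n",
              x$w, x$w_stderr, x$b, x$r_squared))
  invisible(x)
}

#' Extrapolated relative energy from the VMC-DMC linear relation
#'
#' Assuming the intercept of the linear relation is common to the two
#' configurations, it cancels in differences and the extrapolated relative
#' energy is `(1 + w) dE_DMC - w dE_VMC`.
#'
#' @param dE_DMC,dE_VMC relative energies (Hartree, or any common unit).
#' @param w fitted slope.
#' @return extrapolated relative energy in the same unit.
#' @export
extrapolate_relative <- function(dE_DMC, dE_VMC, w) {
  (1 + w) * dE_DMC - w * dE_VMC
}

#' Per-step extrapolated relative energies for two systems
#'
#' For two energy trajectories sharing a grid of training steps, fits one
#' pooled slope `w` (stacking both systems' regression points, consistent
#' with the assumption of a common intercept) and applies
#' [extrapolate_relative()] at every shared step.  Averaging the resulting
#' per-step values removes the residual linear-fitting error, so the spread
#' of the extrapolated values is typically much smaller than the spread of
#' the raw DMC differences.
#'
#' @param trajA,trajB [energy_trajectory()] objects (B minus A is reported).
#' @param w optional slope override; default: pooled fit.
#' @return list with `values` (data frame: k, dE_VMC, dE_DMC, dE_ex), `w`,
#'   `mean`, `sd`, `sd_raw_dmc` (spread of the unextrapolated DMC
#'   differences).
#' @export
extrapolation_distribution <- function(trajA, trajB, w = NULL) {
  if (!identical(as.numeric(trajA$k), as.numeric(trajB$k)))
    stop("trajectories must share a common step grid")
  if (nrow(trajA) < 3) stop("need at least 3 shared steps")
  if (is.null(w)) {
    x <- c(trajA$E_VMC - trajA$E_DMC, trajB$E_VMC - trajB$E_DMC)
    y <- c(trajA$E_DMC - trajA$E_DMC[nrow(trajA)],
           trajB$E_DMC - trajB$E_DMC[nrow(trajB)])
    if (diff(range(x)) < 1e-14) stop("degenerate predictor in pooled fit")
    # shared slope, per-system intercept (each trajectory is referenced to
    # its own final DMC energy)
    grp <- factor(rep(c("A", "B"), c(nrow(trajA), nrow(trajB))))
    w <- unname(stats::coef(stats::lm(y ~ x + grp))["x"])
  }
  dE_DMC <- trajB$E_DMC - trajA$E_DMC
  dE_VMC <- trajB$E_VMC - trajA$E_VMC
  dE_ex <- extrapolate_relative(dE_DMC, dE_VMC, w)
  list(values = data.frame(k = trajA$k, dE_VMC = dE_VMC, dE_DMC = dE_DMC,
                           dE_ex = dE_ex),
       w = w, mean = mean(dE_ex), sd = stats::sd(dE_ex),
       sd_raw_dmc = stats::sd(dE_DMC))
}
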