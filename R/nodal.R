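# Nodal-surface geometry: point-to-node distance, psi^2-weighted sampling
# of the node, the divergence between two nodal surfaces, and the slice /
# spherical-cut visualization protocols.

#' Parameters for nodal-divergence estimation
#'
#' @param epsilon half-width of the shell around the node from which
#'   psi^2-weighted samples are drawn (bohr).
#' @param K number of node samples.
#' @param projection_tol bisection tolerance for projecting shell samples
#'   onto the node (bohr, must be < `epsilon`).
#' @param max_line_search maximum marching steps when bracketing a node
#'   along the search ray.
#' @param seed RNG seed.
#' @return validated parameter list.
#' @export
nodal_params <- function(epsilon = 0.1, K = 4096, projection_tol = 1e-4,
                         max_line_search = 200, seed = 1) {
  stopifnot(epsilon > 0, K >= 1, projection_tol > 0,
            projection_tol < epsilon, max_line_search >= 1)
  list(epsilon = epsilon, K = as.integer(K), projection_tol = projection_tol,
       max_line_search = as.integer(max_line_search), seed = as.integer(seed))
}

# first-order distance estimate |psi| / |grad psi| = 1 / |grad log|psi||
#' @keywords internal
node_distance_estimate <- function(trial, X) {
  X <- as_walker_matrix(X)
  g <- trial$grad(X)
  1 / sqrt(rowSums(g^2))
}

#' Distance from a configuration to the nodal surface
#'
#' Approximates the smallest distance from `point` to the zero set of the
#' trial: the first-order estimate `|psi| / |grad psi|` seeds a march along
#' the downhill gradient direction of `log|psi|`; once a sign change is
#' bracketed it is bisected to `tol`, and the witness is polished by a few
#' Newton projections along the local gradient.  The result is an upper
#' bound on the true distance (up to `tol`), since the witness lies on the
#' node.
#'
#' @param trial a `fndmc_trial` (must not be nodeless).
#' @param point configuration vector.
#' @param tol bisection tolerance (bohr).
#' @param max_line_search marching-step budget.
#' @return list with `distance` (bohr; `Inf` when no node is found within
#'   the search range) and `witness` (a configuration on the node, or
#'   `NULL`).
#' @export
distance_to_node <- function(trial, point, tol = 1e-6, max_line_search = 200) {
  if (trial$nodeless) stop("trial is nodeless: no nodal surface exists")
  x0 <- as.numeric(point)
  lp0 <- trial$logpsi(x0)
  if (!is.finite(lp0$log) || lp0$sign == 0)
    return(list(distance = 0, witness = x0))
  s0 <- lp0$sign
  g <- as.numeric(trial$grad(x0))
  gn <- sqrt(sum(g^2))
  d0 <- 1 / gn
  # march with growing steps until the sign flips; the downhill ray is
  # tried first, but when the envelope gradient dominates it can run
  # parallel to the node, so the opposite ray serves as fallback
  bracket <- function(u) {
    step <- d0
    t_cur <- 0
    for (k in seq_len(max_line_search)) {
      t_next <- t_cur + step
      lp <- trial$logpsi(x0 + t_next * u)
      if (!is.finite(lp$log) || lp$sign != s0)
        return(c(t_cur, t_next))
      t_cur <- t_next
      step <- step * 1.3
    }
    NULL
  }
  u <- -g / gn                       # downhill in |psi|
  br <- bracket(u)
  if (is.null(br)) {
    u <- g / gn
    br <- bracket(u)
  }
  if (is.null(br)) return(list(distance = Inf, witness = NULL))
  t_lo <- br[1]; t_hi <- br[2]
  # bisect the bracket to tol
  while (t_hi - t_lo > tol) {
    tm <- (t_lo + t_hi) / 2
    lp <- trial$logpsi(x0 + tm * u)
    if (!is.finite(lp$log) || lp$sign != s0) t_hi <- tm else t_lo <- tm
  }
  z <- x0 + ((t_lo + t_hi) / 2) * u
  # perpendicular polish: the bisection ray need not be normal to the node,
  # so slide the witness along the node's tangent plane towards the foot of
  # the perpendicular from x0, re-projecting onto the node with Newton
  # steps (x <- x - g/|g|^2 with g = grad log|psi| moves to the local zero).
  newton_to_node <- function(p) {
    for (k in 1:6) {
      g <- as.numeric(trial$grad(p))
      g2 <- sum(g^2)
      if (!is.finite(g2) || g2 == 0) return(NULL)
      if (1 / sqrt(g2) < tol / 4) break
      p2 <- p - g / g2
      if (!is.finite(trial$logpsi(p2)$log)) return(NULL)
      p <- p2
    }
    p
  }
  for (it in 1:5) {
    g <- as.numeric(trial$grad(z))
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn == 0) break
    nrm <- g / gn
    v <- x0 - z
    vt <- v - nrm * sum(nrm * v)     # tangential misalignment
    if (sqrt(sum(vt^2)) < tol) break
    z_try <- newton_to_node(z + vt)
    if (is.null(z_try)) break
    if (sum((z_try - x0)^2) >= sum((z - x0)^2)) break
    z <- z_try
  }
  d <- sqrt(sum((z - x0)^2))
  list(distance = d, witness = z)
}

#' Sample configurations on the nodal surface, psi^2-weighted
#'
#' Metropolis sampling of psi^2 restricted to the shell of points whose
#' first-order node-distance estimate is below `epsilon`, followed by
#' projection of every retained sample onto the node through the witness of
#' [distance_to_node()] (the nearest-point map).  This realizes the
#' pushforward of the psi^2 density from the shell onto the surface, so
#' regions of the node with larger nearby |psi| receive more samples.
#'
#' @param trial a `fndmc_trial` with a node.
#' @param system owning system.
#' @param params a [nodal_params()] list.
#' @param n_sweeps Metropolis sweeps between retained samples.
#' @param step_size proposal width (bohr).
#' @return list: `points` (K x n_coords matrix of on-node configurations),
#'   `raw` (the unprojected shell samples), `acceptance`.
#' @export
sample_node_points <- function(trial, system = trial$system,
                               params = nodal_params(), n_sweeps = 5,
                               step_size = 0.4) {
  if (trial$nodeless) stop("trial is nodeless: no nodal surface to sample")
  set.seed(params$seed)
  nc <- n_electrons(system) * system$d
  # find a starting point inside the shell: walk psi^2 samples toward the node
  x <- as.numeric(random_configs(system, 1))
  found <- FALSE
  for (try in 1:200) {
    dn <- distance_to_node(trial, x, tol = params$projection_tol)
    if (is.finite(dn$distance)) {
      # step to just off the witness, inside the shell
      off <- stats::rnorm(nc, sd = params$epsilon / (2 * sqrt(nc)))
      cand <- dn$witness + off
      if (node_distance_estimate(trial, cand) < params$epsilon &&
          is.finite(trial$logpsi(cand)$log)) { x <- cand; found <- TRUE; break }
    }
    x <- as.numeric(random_configs(system, 1))
  }
  if (!found) stop("no node encountered within the step budget; ",
                   "consider a larger epsilon")
  lp <- trial$logpsi(x)
  pts <- matrix(NA_real_, params$K, nc)
  raw <- matrix(NA_real_, params$K, nc)
  n_acc <- 0; n_prop <- 0
  for (k in seq_len(params$K)) {
    for (s in seq_len(n_sweeps)) {
      xp <- x + stats::rnorm(nc, sd = step_size)
      n_prop <- n_prop + 1
      lpp <- trial$logpsi(xp)
      if (is.finite(lpp$log) &&
          node_distance_estimate(trial, xp) < params$epsilon &&
          log(stats::runif(1)) < 2 * (lpp$log - lp$log)) {
        x <- xp; lp <- lpp; n_acc <- n_acc + 1
      }
    }
    raw[k, ] <- x
    pr <- distance_to_node(trial, x, tol = params$projection_tol)
    pts[k, ] <- if (is.finite(pr$distance)) pr$witness else x
  }
  list(points = pts, raw = raw, acceptance = n_acc / n_prop)
}

#' Divergence between two nodal surfaces
#'
#' `D(S1, S2)`: the expected distance from psi1^2-weighted samples on the
#' nodal surface of `trial1` to the nodal surface of `trial2`, estimated as
#' the sample mean of [distance_to_node()] over [sample_node_points()]
#' draws.  Non-negative, and not symmetric in its arguments (it is a
#' divergence, not a metric).
#'
#' @param trial1,trial2 `fndmc_trial` objects on the same system, both with
#'   nodes.
#' @param params a [nodal_params()] list.
#' @return list: `D` (bohr), `stderr` (Monte-Carlo), `distances`
#'   (per-sample), `n_unreached` (samples with no node of `trial2` in
#'   range, excluded from the mean).
#' @export
nodal_divergence <- function(trial1, trial2, params = nodal_params()) {
  sp <- sample_node_points(trial1, params = params)
  ds <- apply(sp$points, 1, function(y)
    distance_to_node(trial2, y, tol = params$projection_tol,
                     max_line_search = params$max_line_search)$distance)
  ok <- is.finite(ds)
  if (!any(ok)) stop("no sample reached the second nodal surface")
  list(D = mean(ds[ok]),
       stderr = stats::sd(ds[ok]) / sqrt(sum(ok)),
       distances = ds[ok],
       n_unreached = sum(!ok))
}

#' Two-dimensional wavefunction slice
#'
#' Moves a single electron over a square grid in a coordinate plane while
#' all other electrons stay fixed, recording the log-magnitude and sign of
#' the trial at each pixel.  Node lines appear as boundaries of the sign
#' mask (and as deep minima of the log-magnitude).
#'
#' @param trial a `fndmc_trial`.
#' @param base_config configuration holding the fixed electrons.
#' @param moving_electron index of the electron that scans the grid.
#' @param plane integer pair: which two coordinates of that electron vary
#'   (default `c(1, 2)`, the x-y plane).
#' @param extent half-width of the square (default 5 bohr, i.e. the square
#'   `[-5, 5]^2`).
#' @param n_grid grid resolution per axis.
#' @param center plane offset for the two varied coordinates.
#' @return list: `x`, `y` (grid axes, bohr), `log_magnitude`, `sign`
#'   (n_grid x n_grid matrices).
#' @export
wavefunction_slice <- function(trial, base_config, moving_electron = 1,
                               plane = c(1, 2), extent = 5, n_grid = 101,
                               center = c(0, 0)) {
  sys <- trial$system
  d <- sys$d
  n <- n_electrons(sys)
  stopifnot(moving_electron >= 1, moving_electron <= n)
  ax <- seq(-extent, extent, length.out = n_grid)
  cols <- d * (moving_electron - 1) + plane
  X <- matrix(rep(as.numeric(base_config), each = n_grid^2), n_grid^2)
  gg <- expand.grid(x = ax + center[1], y = ax + center[2])
  X[, cols[1]] <- gg$x
  X[, cols[2]] <- gg$y
  lp <- trial$logpsi(X)
  list(x = ax + center[1], y = ax + center[2],
       log_magnitude = matrix(lp$log, n_grid, n_grid),
       sign = matrix(lp$sign, n_grid, n_grid))
}

#' Spherical-coordinate nodal cut for a four-electron atom
#'
#' Evaluates the trial over a 3-D grid in `(r1, cos(theta1), r3)` with the
#' remaining spherical coordinates frozen at the standard scan values:
#' `r2 = r4 = 1.1` bohr, `phi1 = phi2 = 0`, `phi3 = pi/2`,
#' `phi4 = 3 pi/2`, `theta2 = theta3 = theta4 = pi/2`.  Grid ranges:
#' `r1, r3` in `[0.1, 2.1]` bohr and `cos(theta1)` in `[-1, 1]`.  The zero
#' set is located by sign changes between neighbouring grid cells.
#'
#' @param trial a `fndmc_trial` for a 4-electron atom.
#' @param n_grid resolution per axis.
#' @return list: `r1`, `costheta1`, `r3` (axes), `field` (signed
#'   wavefunction values, via sign * exp(log)), `sign` (3-D array),
#'   `crossings` (matrix of grid-cell midpoints adjacent to a sign change).
#' @export
be_nodal_cut <- function(trial, n_grid = 31) {
  sys <- trial$system
  if (n_electrons(sys) != 4) stop("spherical cut requires a 4-electron atom")
  r1 <- seq(0.1, 2.1, length.out = n_grid)
  ct1 <- seq(-1, 1, length.out = n_grid)
  r3 <- seq(0.1, 2.1, length.out = n_grid)
  sph <- function(r, theta, phi)
    c(r * sin(theta) * cos(phi), r * sin(theta) * sin(phi), r * cos(theta))
  e2 <- sph(1.1, pi / 2, 0)
  e3dir <- function(r) sph(r, pi / 2, pi / 2)
  e4 <- sph(1.1, pi / 2, 3 * pi / 2)
  gg <- expand.grid(r1 = r1, ct1 = ct1, r3 = r3)
  X <- matrix(0, nrow(gg), 12)
  th1 <- acos(gg$ct1)
  X[, 1] <- gg$r1 * sin(th1)          # phi1 = 0
  X[, 2] <- 0
  X[, 3] <- gg$r1 * gg$ct1
  X[, 4:6] <- matrix(e2, nrow(gg), 3, byrow = TRUE)
  X[, 7] <- 0                          # phi3 = pi/2, theta3 = pi/2
  X[, 8] <- gg$r3
  X[, 9] <- 0
  X[, 10:12] <- matrix(e4, nrow(gg), 3, byrow = TRUE)
  lp <- trial$logpsi(X)
  field <- array(lp$sign * exp(lp$log - max(lp$log[is.finite(lp$log)])),
                 dim = c(n_grid, n_grid, n_grid))
  sgn <- array(lp$sign, dim = c(n_grid, n_grid, n_grid))
  crossings <- NULL
  cr <- which(sgn[-n_grid, , ] * sgn[-1, , ] < 0, arr.ind = TRUE)
  if (nrow(cr)) crossings <- rbind(crossings,
    cbind(r1 = (r1[cr[, 1]] + r1[cr[, 1] + 1]) / 2, ct1 = ct1[cr[, 2]],
          r3 = r3[cr[, 3]]))
  cr <- which(sgn[, -n_grid, ] * sgn[, -1, ] < 0, arr.ind = TRUE)
  if (nrow(cr)) crossings <- rbind(crossings,
    cbind(r1 = r1[cr[, 1]], ct1 = (ct1[cr[, 2]] + ct1[cr[, 2] + 1]) / 2,
          r3 = r3[cr[, 3]]))
  cr <- which(sgn[, , -n_grid] * sgn[, , -1] < 0, arr.ind = TRUE)
  if (nrow(cr)) crossings <- rbind(crossings,
    cbind(r1 = r1[cr[, 1]], ct1 = ct1[cr[, 2]],
          r3 = (r3[cr[, 3]] + r3[cr[, 3] + 1]) / 2))
  list(r1 = r1, costheta1 = ct1, r3 = r3, field = field, sign = sgn,
       crossings = crossings)
}
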