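# Molecular systems, geometry I/O and walker initialization.
# All internal computation is in Hartree atomic units (bohr, Hartree);
# unit conversion happens only at I/O boundaries (XYZ files are Angstrom
# by default, following community convention).

#' Bohr per Angstrom conversion factor
#' @keywords internal
BOHR_PER_ANGSTROM <- 1.8897259886

# Elements H..Ar with ground-state (Hund-rule) spin occupations.
.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  Z      = 1:18,
  n_up   = c(1, 1, 2, 2, 3, 4, 5, 5, 5, 5, 6, 6, 7, 8, 9, 9, 9, 9),
  n_down = c(0, 1, 1, 2, 2, 2, 2, 3, 4, 5, 5, 6, 6, 6, 6, 7, 8, 9),
  stringsAsFactors = FALSE
)

#' Construct a molecular system
#'
#' A `fndmc_system` bundles nuclear positions and charges with the electron
#' counts per spin channel.  Spin is encoded purely by block ordering of the
#' electron coordinates (spin-up block first); no spin coordinates are ever
#' sampled.  Coordinates are in bohr.
#'
#' Test systems without nuclei (harmonic wells, used as analytic fixtures)
#' are supported through the `potential` override and a per-particle
#' dimension `d` other than 3.
#'
#' @param nuclear_positions matrix with one row per nucleus and 3 columns
#'   (bohr), or `NULL` for model systems.
#' @param nuclear_charges numeric vector of positive charges Z_I.
#' @param n_up,n_down electron counts per spin channel.
#' @param label free-text description.
#' @param d spatial dimension per electron (3 for molecules).
#' @param potential optional function `V(X)` mapping a walker matrix (one row
#'   per walker, `n_el * d` columns, electron-major layout) to the potential
#'   energy in Hartree; defaults to the molecular Coulomb potential.
#' @return an object of class `fndmc_system`.
#' @export
make_system <- function(nuclear_positions, nuclear_charges, n_up, n_down,
                        label = "", d = 3, potential = NULL) {
  if (!is.null(nuclear_positions)) {
    nuclear_positions <- matrix(as.numeric(nuclear_positions), ncol = 3)
    if (nrow(nuclear_positions) != length(nuclear_charges))
      stop("number of nuclear positions and charges must agree")
    if (any(nuclear_charges <= 0)) stop("all nuclear charges must be > 0")
  } else if (is.null(potential)) {
    stop("a system without nuclei requires an explicit potential")
  }
  n_up <- as.integer(n_up); n_down <- as.integer(n_down)
  if (n_down < 0 || n_up < n_down) stop("require n_up >= n_down >= 0")
  if (n_up + n_down < 1) stop("at least one electron required")
  sys <- structure(list(
    nuclear_positions = nuclear_positions,
    nuclear_charges = as.numeric(nuclear_charges),
    n_up = n_up, n_down = n_down, d = as.integer(d),
    label = label, potential = potential
  ), class = "fndmc_system")
  sys
}

#' @export
print.fndmc_system <- function(x, ...) {
  cat("<fndmc_system>", x$label, "\n")
  cat("  electrons:", x$n_up, "up +", x$n_down, "down, d =", x$d, "\n")
  if (!is.null(x$nuclear_positions)) {
    cat("  nuclei (bohr):\n")
    for (i in seq_along(x$nuclear_charges))
      cat(sprintf("    Z=%g  (% .6f, % .6f, % .6f)\n", x$nuclear_charges[i],
                  x$nuclear_positions[i, 1], x$nuclear_positions[i, 2],
                  x$nuclear_positions[i, 3]))
  } else cat("  model system (custom potential)\n")
  invisible(x)
}

#' Number of electrons in a system
#' @param system a `fndmc_system`.
#' @return integer electron count.
#' @export
n_electrons <- function(system) system$n_up + system$n_down

#' Potential energy of walker configurations
#'
#' Coulomb potential (electron-nucleus attraction, electron-electron
#' repulsion, nucleus-nucleus repulsion) for molecular systems, or the
#' system's custom potential for model fixtures.
#'
#' @param system a `fndmc_system`.
#' @param X walker matrix: one row per walker, `n_el * d` columns,
#'   electron-major layout `(x1, y1, z1, x2, ...)`.
#' @return numeric vector of potential energies (Hartree), one per walker.
#' @export
potential_energy <- function(system, X) {
  X <- as_walker_matrix(X)
  if (!is.null(system$potential)) return(system$potential(X))
  n <- n_electrons(system)
  W <- nrow(X)
  V <- numeric(W)
  R <- system$nuclear_positions
  Zs <- system$nuclear_charges
  # electron-nucleus attraction
  for (i in seq_len(n)) {
    xi <- X[, 3 * (i - 1) + 1:3, drop = FALSE]
    for (I in seq_along(Zs)) {
      dd <- sqrt((xi[, 1] - R[I, 1])^2 + (xi[, 2] - R[I, 2])^2 +
                 (xi[, 3] - R[I, 3])^2)
      V <- V - Zs[I] / dd
    }
  }
  # electron-electron repulsion
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      xi <- X[, 3 * (i - 1) + 1:3, drop = FALSE]
      xj <- X[, 3 * (j - 1) + 1:3, drop = FALSE]
      dd <- sqrt(rowSums((xi - xj)^2))
      V <- V + 1 / dd
    }
  }
  # nucleus-nucleus repulsion (constant)
  if (length(Zs) > 1) {
    for (I in seq_len(length(Zs) - 1)) for (J in (I + 1):length(Zs)) {
      V <- V + Zs[I] * Zs[J] / sqrt(sum((R[I, ] - R[J, ])^2))
    }
  }
  V
}

#' @keywords internal
as_walker_matrix <- function(X) {
  if (is.matrix(X)) X else matrix(X, nrow = 1)
}

#' Read a molecular geometry from an XYZ file
#'
#' Standard XYZ dialect: a count line, a comment line, then one
#' `element x y z` row per atom.  Coordinates are Angstrom by default and
#' converted to bohr internally.
#'
#' @param path path to the XYZ file.
#' @param n_up,n_down optional spin occupation override.  Default: total
#'   electrons equal the total nuclear charge, with the ceiling of n/2
#'   assigned spin-up.
#' @param units `"angstrom"` (default) or `"bohr"`.
#' @return a `fndmc_system` (coordinates in bohr).
#' @export
load_xyz <- function(path, n_up = NULL, n_down = NULL,
                     units = c("angstrom", "bohr")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (length(lines) < 3) stop("XYZ parse error: file too short")
  n_at <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n_at) || n_at < 1)
    stop("XYZ parse error at line 1: invalid atom count")
  rows <- lines[-(1:2)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != n_at)
    stop(sprintf("XYZ parse error: header declares %d atoms but %d rows found",
                 n_at, length(rows)))
  pos <- matrix(NA_real_, n_at, 3)
  Zs <- numeric(n_at)
  for (k in seq_len(n_at)) {
    tok <- strsplit(trimws(rows[k]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", k + 2))
    m <- match(tok[1], .element_table$symbol)
    if (is.na(m))
      stop(sprintf("XYZ parse error at line %d: unknown element symbol '%s'",
                   k + 2, tok[1]))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop(sprintf("XYZ parse error at line %d: malformed coordinate", k + 2))
    pos[k, ] <- xyz
    Zs[k] <- .element_table$Z[m]
  }
  if (units == "angstrom") pos <- pos * BOHR_PER_ANGSTROM
  ne <- sum(Zs)
  if (is.null(n_up)) n_up <- ceiling(ne / 2)
  if (is.null(n_down)) n_down <- ne - n_up
  make_system(pos, Zs, n_up, n_down, label = basename(path))
}

#' Write a molecular geometry to an XYZ file
#'
#' @param system a `fndmc_system` with nuclei.
#' @param path output path.
#' @param units `"angstrom"` (default) or `"bohr"`.
#' @param comment comment line text.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path, units = c("angstrom", "bohr"),
                      comment = system$label) {
  units <- match.arg(units)
  if (is.null(system$nuclear_positions)) stop("system has no nuclei")
  pos <- system$nuclear_positions
  if (units == "angstrom") pos <- pos / BOHR_PER_ANGSTROM
  sym <- .element_table$symbol[match(round(system$nuclear_charges),
                                     .element_table$Z)]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(nrow(pos)), comment), con)
  for (k in seq_len(nrow(pos)))
    writeLines(sprintf("%s % .10f % .10f % .10f", sym[k],
                       pos[k, 1], pos[k, 2], pos[k, 3]), con)
  invisible(path)
}

#' Built-in system catalog
#'
#' Atoms H through Ar at the origin with ground-state spin occupations, the
#' nitrogen molecule at a configurable bond length (placed on the z axis,
#' symmetric about the origin), and analytic harmonic-well model fixtures.
#'
#' Harmonic fixtures:
#' \describe{
#'   \item{`harmonic3d`}{one particle in an isotropic 3-D well, params
#'     `omega` (default 1).}
#'   \item{`harmonic1d2f`}{two same-spin fermions in a 1-D well, params
#'     `omega` (default 1); exact ground-state energy `2 omega`.}
#' }
#'
#' @param name catalog identifier (element symbol, `"N2"`, or a harmonic
#'   fixture name).
#' @param params optional list, e.g. `list(bond_length = 2.1)` for N2
#'   (bohr) or `list(omega = 1)` for the wells.
#' @return a `fndmc_system`.
#' @export
builtin_system <- function(name, params = list()) {
  m <- match(name, .element_table$symbol)
  if (!is.na(m)) {
    e <- .element_table[m, ]
    return(make_system(matrix(0, 1, 3), e$Z, e$n_up, e$n_down, label = name))
  }
  if (identical(name, "N2")) {
    bl <- params$bond_length %||% 2.1
    if (!is.numeric(bl) || bl <= 0) stop("N2 bond length must be > 0")
    pos <- rbind(c(0, 0, -bl / 2), c(0, 0, bl / 2))
    return(make_system(pos, c(7, 7), 7, 7,
                       label = sprintf("N2 (d = %g bohr)", bl)))
  }
  if (identical(name, "harmonic3d")) {
    om <- params$omega %||% 1
    return(make_system(NULL, numeric(0), 1, 0, d = 3,
                       label = sprintf("3-D harmonic well (omega = %g)", om),
                       potential = function(X) 0.5 * om^2 * rowSums(X^2)))
  }
  if (identical(name, "harmonic1d2f")) {
    om <- params$omega %||% 1
    return(make_system(NULL, numeric(0), 2, 0, d = 1,
                       label = sprintf("1-D two-fermion well (omega = %g)", om),
                       potential = function(X) 0.5 * om^2 * rowSums(X^2)))
  }
  stop("unknown builtin system: ", name)
}

#' List built-in system names
#' @return character vector of catalog identifiers.
#' @export
list_systems <- function() {
  c(.element_table$symbol, "N2", "harmonic3d", "harmonic1d2f")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize a walker ensemble around the nuclei
#'
#' Electrons are assigned to nuclei proportionally to the nuclear charge
#' (round-robin weighted by Z_I) and their positions drawn from isotropic
#' Gaussians of width `max(1/Z_I, 0.3)` bohr centred on the assigned
#' nucleus.  Model systems without nuclei draw from a unit Gaussian at the
#' origin.  Reproducible given `seed`.
#'
#' @param system a `fndmc_system`.
#' @param n_walkers number of configurations (>= 1).
#' @param seed integer RNG seed.
#' @return matrix of `n_walkers` rows and `n_el * d` columns (bohr),
#'   electron-major layout, spin-up block first.
#' @export
init_walkers <- function(system, n_walkers, seed = 1) {
  if (n_walkers < 1) stop("n_walkers must be >= 1")
  set.seed(seed)
  n <- n_electrons(system)
  d <- system$d
  X <- matrix(0, n_walkers, n * d)
  if (is.null(system$nuclear_positions)) {
    X[] <- stats::rnorm(n_walkers * n * d)
    return(X)
  }
  Zs <- system$nuclear_charges
  # assign electrons to nuclei proportionally to charge: repeat each nucleus
  # index Z_I times (rounded), truncate/recycle to n electrons
  assign_pool <- rep(seq_along(Zs), times = pmax(1, round(Zs)))
  assignment <- rep_len(assign_pool, n)
  for (i in seq_len(n)) {
    I <- assignment[i]
    sd_i <- max(1 / Zs[I], 0.3)
    X[, d * (i - 1) + seq_len(d)] <-
      matrix(stats::rnorm(n_walkers * d, sd = sd_i), n_walkers, d) +
      matrix(system$nuclear_positions[I, seq_len(d)], n_walkers, d, byrow = TRUE)
  }
  X
}
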