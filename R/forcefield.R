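# Interaction laws for the coarse-grained fibril model: breakable trilinear
# bonds, harmonic angle bending, and a soft-core truncated-shifted
# Lennard-Jones pair potential.

#' Bond species used in the fibril topology
#'
#' Order matters: integer species codes elsewhere in the package index into
#' this vector.
#' @export
BOND_SPECIES <- c("backbone", "extension", "ecl_divalent", "ecl_trivalent", "age")

#' Construct a breakable trilinear bond law
#'
#' The tension is piecewise linear in the separation `r`: slope `k0` up to
#' the critical hyperelastic distance `r1`, slope `k1` from there to the
#' breaking distance `r_break`, then a linear ramp from the peak tension down
#' to zero over the regularization width `a = z * (r_break - r1)`. The force
#' is continuous on the whole positive axis and identically zero once `r`
#' exceeds `r_break + a`.
#'
#' @param species label, one of [BOND_SPECIES] (free-form labels allowed for
#'   ad-hoc laws).
#' @param r0 equilibrium separation (Angstrom).
#' @param r1 critical hyperelastic separation (Angstrom), `r0 < r1`.
#' @param r_break breaking separation (Angstrom), `r1 < r_break`.
#' @param k0,k1 tensile stiffnesses of the first two branches
#'   (kcal mol^-1 A^-2), both positive.
#' @param z dimensionless regularization factor in (0, 1) setting the ramp
#'   width.
#' @return an object of class `bond_law`.
#' @export
bond_law <- function(species, r0, r1, r_break, k0, k1, z = 0.05) {
  stopifnot(is.character(species), length(species) == 1L)
  vals <- c(r0 = r0, r1 = r1, r_break = r_break, k0 = k0, k1 = k1, z = z)
  if (any(!is.finite(vals))) stop("bond_law: all parameters must be finite")
  if (!(r0 < r1 && r1 < r_break)) {
    stop("bond_law: need r0 < r1 < r_break (got ",
         paste(signif(c(r0, r1, r_break), 6), collapse = " < "), ")")
  }
  if (k0 <= 0 || k1 <= 0) stop("bond_law: stiffnesses must be positive")
  if (z <= 0 || z >= 1) stop("bond_law: z must lie in (0, 1)")
  a <- z * (r_break - r1)
  t_peak <- k0 * (r1 - r0) + k1 * (r_break - r1)
  structure(
    list(species = species, r0 = r0, r1 = r1, r_break = r_break,
         k0 = k0, k1 = k1, z = z, a = a, t_peak = t_peak),
    class = "bond_law")
}

#' @export
print.bond_law <- function(x, ...) {
  cat(sprintf("<bond_law '%s'> r0=%.2f r1=%.2f r_break=%.2f A | k0=%.2f k1=%.2f kcal/mol/A^2 | z=%.3g (ramp %.3g A)\n",
              x$species, x$r0, x$r1, x$r_break, x$k0, x$k1, x$z, x$a))
  invisible(x)
}

#' Bond tension as a function of separation
#'
#' Signed scalar force in kcal mol^-1 A^-1; positive values are restoring
#' (pulling the pair back toward `r0`) for stretched bonds, negative for
#' compressed ones.
#'
#' @param r separations (Angstrom), vectorized.
#' @param law a [bond_law()].
#' @return numeric vector of tensions.
#' @export
bond_force <- function(r, law) {
  stopifnot(inherits(law, "bond_law"))
  if (any(!is.finite(r))) stop("bond_force: non-finite separation")
  if (any(r <= 0)) stop("bond_force: separations must be positive")
  f <- numeric(length(r))
  t1 <- law$k0 * (law$r1 - law$r0)
  b1 <- r < law$r1
  b2 <- !b1 & r < law$r_break
  b3 <- !b1 & !b2 & r < law$r_break + law$a
  f[b1] <- law$k0 * (r[b1] - law$r0)
  f[b2] <- t1 + law$k1 * (r[b2] - law$r1)
  f[b3] <- law$t_peak * (1 - (r[b3] - law$r_break) / law$a)
  f
}

#' Bond stretching energy
#'
#' Continuous antiderivative of minus [bond_force()] with `energy(r0) = 0`;
#' constant (the total work to rupture) beyond `r_break + a`.
#'
#' @inheritParams bond_force
#' @return numeric vector of energies (kcal mol^-1).
#' @export
bond_energy <- function(r, law) {
  stopifnot(inherits(law, "bond_law"))
  if (any(!is.finite(r))) stop("bond_energy: non-finite separation")
  if (any(r <= 0)) stop("bond_energy: separations must be positive")
  t1 <- law$k0 * (law$r1 - law$r0)
  e1 <- function(x) 0.5 * law$k0 * (x - law$r0)^2
  e_r1 <- e1(law$r1)
  e2 <- function(x) e_r1 + t1 * (x - law$r1) + 0.5 * law$k1 * (x - law$r1)^2
  e_rb <- e2(law$r_break)
  e3 <- function(x) {
    d <- x - law$r_break
    e_rb + law$t_peak * d - law$t_peak / (2 * law$a) * d^2
  }
  e_plateau <- e_rb + 0.5 * law$t_peak * law$a
  e <- numeric(length(r))
  b1 <- r < law$r1
  b2 <- !b1 & r < law$r_break
  b3 <- !b1 & !b2 & r < law$r_break + law$a
  b4 <- r >= law$r_break + law$a
  e[b1] <- e1(r[b1])
  e[b2] <- e2(r[b2])
  e[b3] <- e3(r[b3])
  e[b4] <- e_plateau
  e
}

#' Construct a harmonic angle-bending law
#'
#' @param k_bend bending stiffness (kcal mol^-1 rad^-2).
#' @param phi0_deg equilibrium angle in degrees (per-triplet values are
#'   stored in the topology; this is the default).
#' @param convention `"double"` for `E = k (phi - phi_i)^2` (the package
#'   default) or `"half"` for `E = k/2 (phi - phi_i)^2`.
#' @return an object of class `angle_law`.
#' @export
angle_law <- function(k_bend, phi0_deg = 180, convention = c("double", "half")) {
  convention <- match.arg(convention)
  stopifnot(is.finite(k_bend), k_bend > 0)
  structure(list(k_bend = k_bend, phi0_deg = phi0_deg,
                 convention = convention,
                 factor = if (convention == "double") 2 else 1),
            class = "angle_law")
}

#' Angle bending energy
#'
#' @param phi_deg angle in degrees, vectorized.
#' @param law an [angle_law()].
#' @param phi0_deg equilibrium angle(s) in degrees; defaults to the law's.
#' @return energies (kcal mol^-1).
#' @export
angle_energy <- function(phi_deg, law, phi0_deg = law$phi0_deg) {
  stopifnot(inherits(law, "angle_law"))
  dphi <- (phi_deg - phi0_deg) * pi / 180
  0.5 * law$factor * law$k_bend * dphi^2
}

#' Restoring moment of the angle law
#'
#' Returns `d E / d phi` (kcal mol^-1 rad^-1), i.e. `factor * k_bend *
#' (phi - phi_i)` with the angle difference in radians. It vanishes at
#' `phi = phi_i` and drives the triplet back toward the equilibrium angle.
#'
#' @inheritParams angle_energy
#' @export
angle_moment <- function(phi_deg, law, phi0_deg = law$phi0_deg) {
  stopifnot(inherits(law, "angle_law"))
  if (any(!is.finite(phi_deg)) || any(phi_deg <= 0) || any(phi_deg >= 360)) {
    stop("angle_moment: angles must be finite and in (0, 360) degrees")
  }
  law$factor * law$k_bend * (phi_deg - phi0_deg) * pi / 180
}

#' Construct a soft-core Lennard-Jones pair law
#'
#' Standard 12-6 interaction down to `lambda * sigma`; below that the force
#' is held constant at its value at `lambda * sigma` (soft core). The
#' potential is truncated at `cutoff` and shifted so the energy is zero
#' there; the corresponding force is zero beyond the cutoff.
#'
#' @param epsilon well depth (kcal mol^-1).
#' @param sigma zero-crossing distance of the unshifted potential (Angstrom).
#' @param lambda soft-core parameter in (0, 1].
#' @param cutoff cutoff distance (Angstrom); default `2.5 * sigma`.
#' @return an object of class `pair_law`.
#' @export
pair_law <- function(epsilon, sigma, lambda = 0.9, cutoff = 2.5 * sigma) {
  stopifnot(is.finite(epsilon), epsilon > 0, is.finite(sigma), sigma > 0,
            is.finite(lambda), lambda > 0, lambda <= 1,
            is.finite(cutoff), cutoff > sigma)
  lj_u <- function(r) 4 * epsilon * ((sigma / r)^12 - (sigma / r)^6)
  lj_f <- function(r) 24 * epsilon * (2 * (sigma / r)^12 - (sigma / r)^6) / r
  r_soft <- lambda * sigma
  structure(list(epsilon = epsilon, sigma = sigma, lambda = lambda,
                 cutoff = cutoff, r_soft = r_soft,
                 f_soft = lj_f(r_soft), u_soft = lj_u(r_soft),
                 u_shift = -lj_u(cutoff)),
            class = "pair_law")
}

#' Pair force (soft-core Lennard-Jones)
#'
#' Signed radial force in kcal mol^-1 A^-1, positive = repulsive. Constant
#' at its `lambda * sigma` value below the soft-core radius, zero beyond the
#' cutoff.
#'
#' @param r separations (Angstrom), vectorized, all positive.
#' @param law a [pair_law()].
#' @export
pair_force <- function(r, law) {
  stopifnot(inherits(law, "pair_law"))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("pair_force: separations must be positive and finite")
  }
  f <- numeric(length(r))
  soft <- r < law$r_soft
  mid <- !soft & r <= law$cutoff
  f[soft] <- law$f_soft
  s6 <- (law$sigma / r[mid])^6
  f[mid] <- 24 * law$epsilon * (2 * s6^2 - s6) / r[mid]
  f
}

#' Pair energy (soft-core Lennard-Jones)
#'
#' By default the truncated-and-shifted energy used by the simulation engine
#' (zero at the cutoff). With `shifted = FALSE` the bare potential is
#' returned, which crosses zero exactly at `sigma`.
#'
#' @inheritParams pair_force
#' @param shifted apply the cutoff energy shift (default `TRUE`).
#' @export
pair_energy <- function(r, law, shifted = TRUE) {
  stopifnot(inherits(law, "pair_law"))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("pair_energy: separations must be positive and finite")
  }
  shift <- if (shifted) law$u_shift else 0
  u <- numeric(length(r))
  soft <- r < law$r_soft
  mid <- !soft & r <= law$cutoff
  u[soft] <- law$u_soft + shift + law$f_soft * (law$r_soft - r[soft])
  s6 <- (law$sigma / r[mid])^6
  u[mid] <- 4 * law$epsilon * (s6^2 - s6) + shift
  u
}

#' Load the default force field
#'
#' Reads the versioned parameter file shipped with the package (bond laws
#' for the five species, bending stiffness, pair interaction, particle
#' mass). Any field can be overridden through a nested list, e.g.
#' `list(pair = list(cutoff_factor = 2.0))` or
#' `list(bonds = list(age = list(k1 = 10)))`.
#'
#' @param overrides nested named list of overrides, or `NULL`.
#' @param file alternative parameter file (YAML with the same layout).
#' @return an object of class `forcefield`: `$bonds` (named list of
#'   [bond_law()]), `$angle` ([angle_law()]), `$pair` ([pair_law()]),
#'   `$mass` (amu).
#' @export
default_forcefield <- function(overrides = NULL, file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "forcefield_params.yaml", package = "fibrilmd")
  }
  pars <- yaml::read_yaml(file)
  if (!is.null(overrides)) pars <- utils::modifyList(pars, overrides)
  bonds <- lapply(names(pars$bonds), function(sp) {
    b <- pars$bonds[[sp]]
    bond_law(sp, r0 = b$r0, r1 = b$r1, r_break = b$r_break,
             k0 = b$k0, k1 = b$k1, z = b$z)
  })
  names(bonds) <- names(pars$bonds)
  if (!all(BOND_SPECIES %in% names(bonds))) {
    stop("forcefield file must define laws for: ",
         paste(BOND_SPECIES, collapse = ", "))
  }
  conv <- if (is.null(pars$angle$convention)) "double" else pars$angle$convention
  structure(
    list(bonds = bonds[BOND_SPECIES],
         angle = angle_law(pars$angle$k_bend, convention = conv),
         pair = pair_law(pars$pair$epsilon, pars$pair$sigma, pars$pair$lambda,
                         cutoff = pars$pair$cutoff_factor * pars$pair$sigma),
         mass = pars$mass,
         version = pars$version),
    class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("<forcefield v%s> %d bond species | kB=%.2f kcal/mol/rad^2 (%s) | LJ eps=%.2f sigma=%.2f lambda=%.2f rc=%.2f | mass=%.1f amu\n",
              x$version, length(x$bonds), x$angle$k_bend, x$angle$convention,
              x$pair$epsilon, x$pair$sigma, x$pair$lambda, x$pair$cutoff, x$mass))
  invisible(x)
}

# Flatten the per-species bond laws into the 5 x 8 matrix consumed by the
# compiled engine (rows follow BOND_SPECIES order).
ff_law_matrix <- function(ff) {
  m <- t(vapply(ff$bonds[BOND_SPECIES], function(l) {
    c(l$r0, l$r1, l$r_break, l$k0, l$k1, l$z, l$a, l$t_peak)
  }, numeric(8)))
  colnames(m) <- c("r0", "r1", "r_break", "k0", "k1", "z", "a", "t_peak")
  m
}

#' Total potential energy of a configuration
#'
#' Sums the stretching, bending and pair contributions over an assembled
#' system/topology, honouring broken-bond states (a severed bond contributes
#' its rupture plateau) and the bonded-pair exclusions of the pair sum.
#'
#' @param system a particle system (see [build_fibril()]).
#' @param topology the matching topology.
#' @param ff a [default_forcefield()] object.
#' @param method `"cell"` (neighbour list) or `"brute"` (O(N^2) reference).
#' @return named list with `e_bond`, `e_angle`, `e_inter`, `e_total`
#'   (kcal mol^-1).
#' @export
total_energy <- function(system, topology, ff, method = c("cell", "brute")) {
  method <- match.arg(method)
  fr <- compute_forces(system, topology, ff, method = method, energies = TRUE)
  list(e_bond = fr$e_bond, e_angle = fr$e_angle, e_inter = fr$e_inter,
       e_total = fr$e_bond + fr$e_angle + fr$e_inter)
}

#' Forces (and optionally energies) on every bead
#'
#' Thin wrapper around the compiled force kernel. Mainly used by tests and
#' the minimizer; dynamics run entirely in compiled code.
#'
#' @inheritParams total_energy
#' @param energies also accumulate potential-energy components.
#' @return list with `forces` (N x 3 matrix, kcal mol^-1 A^-1) and, if
#'   requested, `e_bond`, `e_angle`, `e_inter`.
#' @export
compute_forces <- function(system, topology, ff, method = c("cell", "brute"),
                           energies = FALSE) {
  method <- match.arg(method)
  ct <- compiled_topology(system, topology, ff)
  res <- cg_forces(system$pos, ct$bond_i, ct$bond_j, ct$bond_species,
                   ct$bond_state, ff_law_matrix(ff),
                   ct$angle_i, ct$angle_j, ct$angle_k, ct$angle_phi0,
                   ff$angle$k_bend, ff$angle$factor,
                   ff$pair$epsilon, ff$pair$sigma, ff$pair$lambda,
                   ff$pair$cutoff, method == "brute", energies)
  res
}

# Validate and flatten a topology into the 0-based integer arrays the
# compiled code consumes.
compiled_topology <- function(system, topology, ff) {
  n <- nrow(system$pos)
  b <- topology$bonds
  if (nrow(b) > 0 && (max(b$i, b$j) > n || min(b$i, b$j) < 1)) {
    stop("topology refers to bead indices outside the system")
  }
  a <- topology$angles
  if (nrow(a) > 0 && (max(a$i, a$j, a$k) > n || min(a$i, a$j, a$k) < 1)) {
    stop("topology angle triplet refers to beads outside the system")
  }
  sp <- match(b$species, BOND_SPECIES)
  if (any(is.na(sp))) stop("unknown bond species in topology")
  list(bond_i = as.integer(b$i - 1L), bond_j = as.integer(b$j - 1L),
       bond_species = as.integer(sp - 1L),
       bond_state = as.integer(b$state),
       angle_i = as.integer(a$i - 1L), angle_j = as.integer(a$j - 1L),
       angle_k = as.integer(a$k - 1L),
       angle_phi0 = as.numeric(a$phi0_deg) * pi / 180)
}
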