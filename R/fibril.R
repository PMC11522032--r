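# Fibril geometry: staggered D-periodic assembly of bead-spring
# tropocollagen molecules over a triangular cross-section lattice.

#' Specification of a fibril geometry
#'
#' Defaults reproduce the published model: 218 beads per molecule at
#' 14.0 A spacing, a 20.2 nm circular cross-section meshed with a
#' triangular lattice, 67 nm D-period with a 0.6 D gap zone, stagger
#' offsets of whole multiples of D between neighbouring lattice sites, 40
#' reinforced extension beads at each line end and 10-bead rigid clamps.
#'
#' @param n_beads helical beads per molecule.
#' @param r0 bead spacing (Angstrom); equals the backbone equilibrium
#'   distance.
#' @param diameter fibril diameter (Angstrom).
#' @param lattice_spacing triangular-mesh spacing of the cross-section
#'   (Angstrom). The default is tuned so the full 20.2 nm cross-section
#'   hosts the published count of 155 molecules.
#' @param d_period axial D-period (Angstrom).
#' @param gap_fraction fraction of D occupied by the gap zone; the overlap
#'   fraction is `1 - gap_fraction`.
#' @param molecules_per_line molecules placed end-to-end (separated by the
#'   gap) on each lattice line. The published system has one; two or more
#'   add end-to-end gap junctions along each line.
#' @param n_extension reinforced extension beads appended at each end of
#'   every lattice line.
#' @param n_clamp beads per chain end recruited into each rigid clamp.
#' @param clamp_window chains whose terminal bead lies within this axial
#'   distance of the fibril end are clamped there (default: one D-period).
#' @param waviness_deg maximum turning angle between consecutive segments
#'   (degrees). 10 makes the sampled equilibrium angles span 170-180 degrees;
#'   0 builds perfectly straight molecules.
#' @param waviness_wavelength wavelength (in beads) of the slow modulation
#'   of the zigzag amplitude.
#' @param seed RNG seed for the waviness phases.
#' @return an object of class `fibril_spec`.
#' @export
fibril_spec <- function(n_beads = 218, r0 = 14.0, diameter = 202,
                        lattice_spacing = 15.45, d_period = 670,
                        gap_fraction = 0.6, molecules_per_line = 1,
                        n_extension = 40, n_clamp = 10,
                        clamp_window = NULL,
                        waviness_deg = 10, waviness_wavelength = 40,
                        seed = 1L) {
  stopifnot(n_beads >= 10, r0 > 0, diameter > 2 * lattice_spacing,
            d_period > 0, gap_fraction > 0, gap_fraction < 1,
            molecules_per_line >= 1, n_extension >= 0, n_clamp >= 1,
            waviness_deg >= 0, waviness_deg <= 10, waviness_wavelength >= 3)
  if (is.null(clamp_window)) clamp_window <- d_period
  structure(list(
    n_beads = as.integer(n_beads), r0 = r0, diameter = diameter,
    lattice_spacing = lattice_spacing, d_period = d_period,
    gap_fraction = gap_fraction, overlap_fraction = 1 - gap_fraction,
    molecules_per_line = as.integer(molecules_per_line),
    n_extension = as.integer(n_extension), n_clamp = as.integer(n_clamp),
    clamp_window = clamp_window, waviness_deg = waviness_deg,
    waviness_wavelength = waviness_wavelength, seed = as.integer(seed)),
    class = "fibril_spec")
}

#' @export
print.fibril_spec <- function(x, ...) {
  cat(sprintf("<fibril_spec> %d beads/molecule @ %.1f A | d=%.0f A, mesh %.2f A | D=%.0f A (gap %.1f D) | %d mol/line | ext %d, clamp %d\n",
              x$n_beads, x$r0, x$diameter, x$lattice_spacing, x$d_period,
              x$gap_fraction, x$molecules_per_line, x$n_extension, x$n_clamp))
  invisible(x)
}

#' Triangular-lattice sites of the fibril cross-section
#'
#' Points of a triangular lattice (one site at the axis) whose distance
#' from the axis does not exceed `diameter / 2`, in a deterministic order
#' (by distance from the axis, then by polar angle).
#'
#' @param diameter cross-section diameter (Angstrom).
#' @param spacing lattice spacing (Angstrom).
#' @return matrix with columns `y`, `z`.
#' @export
mesh_cross_section <- function(diameter, spacing) {
  stopifnot(diameter > 2 * spacing, spacing > 0)
  rmax <- diameter / 2
  jmax <- ceiling(rmax / (spacing * sqrt(3) / 2)) + 1L
  kmax <- ceiling(rmax / spacing) + 1L
  pts <- do.call(rbind, lapply(-jmax:jmax, function(j) {
    y <- j * spacing * sqrt(3) / 2
    x <- ((-kmax:kmax) + (j %% 2) / 2) * spacing
    cbind(y = x, z = y)
  }))
  d2 <- pts[, 1]^2 + pts[, 2]^2
  pts <- pts[d2 <= rmax^2 + 1e-9, , drop = FALSE]
  ord <- order(round(sqrt(pts[, 1]^2 + pts[, 2]^2), 6),
               round(atan2(pts[, 2], pts[, 1]), 6))
  pts[ord, , drop = FALSE]
}

#' Build a single bead-spring molecule
#'
#' Beads are placed by marching along a gently turning tangent so that
#' consecutive beads are exactly `r0` apart; the turning angle is a
#' sinusoid of amplitude `waviness_deg` in a random plane containing the
#' axial direction. Per-triplet angles of the generated geometry serve as
#' the equilibrium angles downstream; with the default amplitude they span
#' 170-180 degrees.
#'
#' @param spec a [fibril_spec()].
#' @param axial_offset axial coordinate of the first helical bead.
#' @param site transverse coordinates `c(y, z)` of the lattice line.
#' @param ext_left,ext_right append the reinforced extension at this end.
#' @return list with `pos` (n x 3), `zone` (character:
#'   `"extension"`, `"telopeptide"`, `"helical"`), `n_helical`.
#' @export
build_molecule <- function(spec, axial_offset = 0, site = c(0, 0),
                           ext_left = TRUE, ext_right = TRUE) {
  n <- spec$n_beads
  r0 <- spec$r0
  amp <- spec$waviness_deg * pi / 180
  lam <- spec$waviness_wavelength
  phase <- stats::runif(1, 0, 2 * pi)
  tdir <- stats::runif(1, 0, 2 * pi)  # orientation of the waviness plane
  # Tangent angle of each segment: an alternating-sign zigzag whose
  # amplitude is modulated slowly, so consecutive-segment turns reach up
  # to waviness_deg (angles span [180 - waviness_deg, 180]) while the
  # lateral excursion stays below ~ r0 * amp / 2 (about 1 A).
  k <- 0:(n - 2)
  theta <- if (amp > 0) {
    (amp / 2) * (-1)^k * sin(2 * pi * k / lam + phase)
  } else rep(0, n - 1)
  seg <- cbind(cos(theta), sin(theta) * cos(tdir), sin(theta) * sin(tdir)) * r0
  pos <- rbind(c(0, 0, 0), apply(seg, 2, cumsum))
  pos[, 1] <- pos[, 1] + axial_offset
  pos[, 2] <- pos[, 2] + site[1]
  pos[, 3] <- pos[, 3] + site[2]
  zone <- rep("helical", n)
  zone[c(1:4, (n - 3):n)] <- "telopeptide"
  if (ext_left && spec$n_extension > 0) {
    xl <- pos[1, 1] - r0 * (spec$n_extension:1)
    pos <- rbind(cbind(xl, pos[1, 2], pos[1, 3]), pos)
    zone <- c(rep("extension", spec$n_extension), zone)
  }
  if (ext_right && spec$n_extension > 0) {
    xr <- pos[nrow(pos), 1] + r0 * (1:spec$n_extension)
    pos <- rbind(pos, cbind(xr, pos[nrow(pos), 2], pos[nrow(pos), 3]))
    zone <- c(zone, rep("extension", spec$n_extension))
  }
  dimnames(pos) <- NULL
  phi <- triplet_angles(pos)
  bad <- which(phi < 170 - 1e-9)
  if (length(bad) > 0) {
    stop("build_molecule: waviness produced an equilibrium angle below 170 degrees at triplet ", bad[1])
  }
  list(pos = pos, zone = zone, n_helical = n)
}

# Interior angles (degrees) of consecutive bead triplets along a chain.
triplet_angles <- function(pos) {
  n <- nrow(pos)
  if (n < 3) return(numeric(0))
  a <- pos[1:(n - 2), , drop = FALSE] - pos[2:(n - 1), , drop = FALSE]
  b <- pos[3:n, , drop = FALSE] - pos[2:(n - 1), , drop = FALSE]
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

#' Assemble a staggered collagen fibril
#'
#' Places one or more molecules on every lattice site of the cross-section.
#' Site `k` (in the deterministic mesh ordering) is staggered axially by
#' `(k mod 5) * D`; successive molecules on the same line are separated by
#' a gap of `gap_fraction * D`. Line ends receive the reinforced extension
#' beads, and the outermost `n_clamp` beads of every chain ending within
#' `clamp_window` of a fibril end are marked as that end's rigid clamp.
#'
#' @param spec a [fibril_spec()].
#' @param mass bead mass (amu).
#' @return an object of class `fibril`: list with `system` (`pos`, `vel`,
#'   `molecule`, `role`, `clamp_group`, `mass`), `topology` (`bonds`,
#'   `angles` data frames), `spec`, `area` (A^2), `placement`,
#'   `n_molecules`.
#' @export
build_fibril <- function(spec, mass = 1358.7) {
  stopifnot(inherits(spec, "fibril_spec"))
  set.seed(spec$seed)
  sites <- mesh_cross_section(spec$diameter, spec$lattice_spacing)
  n_sites <- nrow(sites)
  stagger <- (seq_len(n_sites) - 1L) %% 5L
  period <- (spec$n_beads - 1) * spec$r0 + spec$gap_fraction * spec$d_period
  pos_l <- list(); zone_l <- list(); mol_l <- list()
  placement <- NULL
  mol_id <- 0L
  for (k in seq_len(n_sites)) {
    for (m in seq_len(spec$molecules_per_line)) {
      mol_id <- mol_id + 1L
      offset <- stagger[k] * spec$d_period + (m - 1) * period
      bm <- build_molecule(spec, axial_offset = offset, site = sites[k, ],
                           ext_left = (m == 1L),
                           ext_right = (m == spec$molecules_per_line))
      pos_l[[mol_id]] <- bm$pos
      zone_l[[mol_id]] <- bm$zone
      mol_l[[mol_id]] <- rep(mol_id, nrow(bm$pos))
      ext_l <- (m == 1L); ext_r <- (m == spec$molecules_per_line)
      placement <- rbind(placement,
                         data.frame(molecule = mol_id, site = k,
                                    stagger = stagger[k],
                                    axial_start = offset,
                                    start_ideal = offset -
                                      (if (ext_l) spec$n_extension * spec$r0 else 0),
                                    end_ideal = offset + (spec$n_beads - 1) * spec$r0 +
                                      (if (ext_r) spec$n_extension * spec$r0 else 0)))
    }
  }
  pos <- do.call(rbind, pos_l)
  zone <- unlist(zone_l)
  molecule <- unlist(mol_l)
  n <- nrow(pos)

  # bonds and angles: consecutive beads/triplets within each chain
  bonds_l <- list(); angles_l <- list()
  idx0 <- 0L
  for (i in seq_along(pos_l)) {
    nm <- nrow(pos_l[[i]])
    zi <- zone_l[[i]]
    bi <- idx0 + seq_len(nm - 1)
    bj <- bi + 1L
    sp <- ifelse(zi[bi - idx0] == "extension" | zi[bj - idx0] == "extension",
                 "extension", "backbone")
    bonds_l[[i]] <- data.frame(i = bi, j = bj, species = sp,
                               stringsAsFactors = FALSE)
    if (nm >= 3) {
      phi <- triplet_angles(pos_l[[i]])
      angles_l[[i]] <- data.frame(i = idx0 + seq_len(nm - 2),
                                  j = idx0 + seq_len(nm - 2) + 1L,
                                  k = idx0 + seq_len(nm - 2) + 2L,
                                  phi0_deg = phi)
    }
    idx0 <- idx0 + nm
  }
  bonds <- do.call(rbind, bonds_l)
  bonds$state <- 0L
  angles <- do.call(rbind, angles_l)

  # clamp capture on the ideal placement grid (robust to waviness jitter)
  role <- zone
  clamp_group <- integer(n)
  xmin <- min(placement$start_ideal); xmax <- max(placement$end_ideal)
  for (q in seq_len(nrow(placement))) {
    mid <- placement$molecule[q]
    sel <- which(molecule == mid)
    xs <- pos[sel, 1]
    if (placement$start_ideal[q] <= xmin + spec$clamp_window) {
      cl <- sel[order(xs)][seq_len(spec$n_clamp)]
      clamp_group[cl] <- 1L
      role[cl] <- "clamp"
    }
    if (placement$end_ideal[q] >= xmax - spec$clamp_window) {
      cl <- sel[order(xs, decreasing = TRUE)][seq_len(spec$n_clamp)]
      clamp_group[cl] <- 2L
      role[cl] <- "clamp"
    }
  }
  if (!any(clamp_group == 1L) || !any(clamp_group == 2L)) {
    stop("build_fibril: no chains reach one of the fibril ends; widen clamp_window")
  }

  structure(list(
    system = list(pos = pos, vel = matrix(0, n, 3), molecule = molecule,
                  role = role, clamp_group = clamp_group,
                  mass = rep(mass, n)),
    topology = list(bonds = bonds, angles = angles),
    spec = spec, area = pi * spec$diameter^2 / 4,
    placement = placement, n_molecules = mol_id),
    class = "fibril")
}

#' @export
print.fibril <- function(x, ...) {
  cat(sprintf("<fibril> %d molecules, %d beads | %d bonds, %d angles | area %.0f A^2 | axial span %.0f A\n",
              x$n_molecules, nrow(x$system$pos), nrow(x$topology$bonds),
              nrow(x$topology$angles), x$area,
              diff(range(x$system$pos[, 1]))))
  invisible(x)
}

#' Measured axial banding period
#'
#' Median difference between consecutive distinct axial start positions of
#' the staggered molecules; for the default stagger assignment this is the
#' D-period.
#'
#' @param fibril a [build_fibril()] result.
#' @export
measure_banding <- function(fibril) {
  first <- fibril$placement[!duplicated(fibril$placement$site), ]
  starts <- sort(unique(first$axial_start))
  if (length(starts) < 2) return(NA_real_)
  stats::median(diff(starts))
}

#' Measured gap lengths along each lattice line
#'
#' Axial distance between the last helical bead of one molecule and the
#' first helical bead of the next molecule on the same line. Only defined
#' when `molecules_per_line >= 2`.
#'
#' @param fibril a [build_fibril()] result.
#' @return numeric vector of measured gaps (Angstrom).
#' @export
measure_line_gaps <- function(fibril) {
  pl <- fibril$placement
  sys <- fibril$system
  gaps <- c()
  for (s in unique(pl$site)) {
    mols <- pl$molecule[pl$site == s]
    if (length(mols) < 2) next
    mols <- mols[order(pl$axial_start[pl$site == s])]
    for (q in seq_len(length(mols) - 1)) {
      sel_a <- sys$molecule == mols[q] & sys$role != "extension" & sys$role != "clamp"
      sel_b <- sys$molecule == mols[q + 1] & sys$role != "extension" & sys$role != "clamp"
      gaps <- c(gaps, min(sys$pos[sel_b, 1]) - max(sys$pos[sel_a, 1]))
    }
  }
  gaps
}

#' Deterministic miniature systems for tests and demos
#'
#' * `"dimer"`: two beads joined by one bond (`species`, separation `r`,
#'    defaults to the species' equilibrium distance), each bead its own
#'    molecule and one-bead clamp.
#' * `"angle_triplet"`: three beads at a configurable angle `phi` with two
#'    backbone bonds and one angle (equilibrium `phi0`).
#' * `"two_molecule"`: two parallel straight chains of `n` beads one
#'    lattice spacing apart.
#' * `"mini_fibril"`: 7 lattice sites, one full-length molecule per
#'    line -- the desk-scale fibril used throughout the tests.
#'
#' @param kind fixture name.
#' @param ff force field (for equilibrium distances).
#' @param ... overrides: `r`, `species`, `phi`, `phi0`, `n`, `seed`, or any
#'   [fibril_spec()] field for `"mini_fibril"`.
#' @return a `fibril` object.
#' @export
make_fixture <- function(kind = c("dimer", "angle_triplet", "two_molecule",
                                  "mini_fibril"),
                         ff = default_forcefield(), ...) {
  kind <- match.arg(kind)
  ov <- list(...)
  mass <- ff$mass
  if (kind == "dimer") {
    species <- if (is.null(ov$species)) "backbone" else ov$species
    r <- if (is.null(ov$r)) ff$bonds[[species]]$r0 else ov$r
    pos <- rbind(c(0, 0, 0), c(r, 0, 0))
    sys <- list(pos = pos, vel = matrix(0, 2, 3), molecule = 1:2,
                role = rep("helical", 2), clamp_group = c(1L, 2L),
                mass = rep(mass, 2))
    topo <- list(bonds = data.frame(i = 1L, j = 2L, species = species,
                                    state = 0L, stringsAsFactors = FALSE),
                 angles = data.frame(i = integer(0), j = integer(0),
                                     k = integer(0), phi0_deg = numeric(0)))
    return(structure(list(system = sys, topology = topo, spec = NULL,
                          area = pi * ff$pair$sigma^2 / 4, placement = NULL,
                          n_molecules = 2L), class = "fibril"))
  }
  if (kind == "angle_triplet") {
    phi <- if (is.null(ov$phi)) 175 else ov$phi
    phi0 <- if (is.null(ov$phi0)) phi else ov$phi0
    r0 <- ff$bonds$backbone$r0
    th <- (180 - phi) * pi / 180
    pos <- rbind(c(-r0, 0, 0), c(0, 0, 0), c(r0 * cos(th), r0 * sin(th), 0))
    sys <- list(pos = pos, vel = matrix(0, 3, 3), molecule = rep(1L, 3),
                role = rep("helical", 3), clamp_group = rep(0L, 3),
                mass = rep(mass, 3))
    topo <- list(bonds = data.frame(i = 1:2, j = 2:3,
                                    species = "backbone", state = 0L,
                                    stringsAsFactors = FALSE),
                 angles = data.frame(i = 1L, j = 2L, k = 3L, phi0_deg = phi0))
    return(structure(list(system = sys, topology = topo, spec = NULL,
                          area = pi * ff$pair$sigma^2 / 4, placement = NULL,
                          n_molecules = 1L), class = "fibril"))
  }
  if (kind == "two_molecule") {
    n <- if (is.null(ov$n)) 30L else as.integer(ov$n)
    r0 <- ff$bonds$backbone$r0
    spacing <- if (is.null(ov$spacing)) 15.45 else ov$spacing
    pos <- rbind(cbind((0:(n - 1)) * r0, 0, 0),
                 cbind((0:(n - 1)) * r0, spacing, 0))
    zone <- rep("helical", n)
    zone[c(1:4, (n - 3):n)] <- "telopeptide"
    sys <- list(pos = pos, vel = matrix(0, 2 * n, 3),
                molecule = rep(1:2, each = n), role = rep(zone, 2),
                clamp_group = rep(0L, 2 * n), mass = rep(mass, 2 * n))
    bonds <- data.frame(i = c(1:(n - 1), n + 1:(n - 1)),
                        j = c(2:n, n + 2:n),
                        species = "backbone", state = 0L,
                        stringsAsFactors = FALSE)
    angles <- data.frame(i = c(1:(n - 2), n + 1:(n - 2)),
                         j = c(2:(n - 1), n + 2:(n - 1)),
                         k = c(3:n, n + 3:n), phi0_deg = 180)
    return(structure(list(system = sys, topology = list(bonds = bonds,
                                                        angles = angles),
                          spec = NULL, area = pi * spacing^2 / 4,
                          placement = NULL, n_molecules = 2L),
                     class = "fibril"))
  }
  # mini_fibril
  args <- list(diameter = 2.1 * 15.45, lattice_spacing = 15.45,
               molecules_per_line = 1, seed = 1L)
  args[names(ov)] <- ov
  spec <- do.call(fibril_spec, args)
  build_fibril(spec, mass = mass)
}

#' Read a reference structure as per-molecule spline control points
#'
#' Optional reader for crystallographic coordinate files (PDB format, e.g.
#' the collagen microfibril model deposited under accession 3HR2). Each
#' chain's alpha-carbon trace is smoothed with a cubic smoothing spline
#' against arc length; the smoothed curves can be resampled at the bead
#' spacing with [resample_curve()] in place of the synthetic waviness. If
#' the file is absent the builder falls back to synthetic geometry.
#'
#' @param path path to a PDB file.
#' @return list of control-point matrices (one per chain), or `NULL` with a
#'   message if the file does not exist.
#' @export
read_reference_structure <- function(path) {
  if (!file.exists(path)) {
    message("reference structure '", path,
            "' not found; falling back to synthetic geometry")
    return(NULL)
  }
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_reference_structure requires the 'bio3d' package")
  }
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("unparsable coordinate file '",
                                           path, "': ", conditionMessage(e)))
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) ca <- pdb$atom
  out <- lapply(split(ca, ca$chain), function(ch) {
    xyz <- as.matrix(ch[, c("x", "y", "z")])
    if (nrow(xyz) < 4) return(xyz)
    s <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
    df <- max(4, min(nrow(xyz) %/% 10, 50))
    sm <- sapply(1:3, function(d) {
      stats::predict(stats::smooth.spline(s, xyz[, d], df = df), s)$y
    })
    unname(sm)
  })
  out
}

#' Resample a curve at equidistant arc-length steps
#'
#' Marches along the piecewise-linear curve through the control points and
#' drops a bead every `spacing` Angstrom, so consecutive beads are exactly
#' `spacing` apart along the curve.
#'
#' @param points n x 3 matrix of control points.
#' @param spacing bead spacing (Angstrom).
#' @return matrix of bead positions.
#' @export
resample_curve <- function(points, spacing) {
  stopifnot(is.matrix(points), ncol(points) == 3, nrow(points) >= 2, spacing > 0)
  out <- points[1, , drop = FALSE]
  cur <- points[1, ]
  i <- 2L
  while (i <= nrow(points)) {
    seg <- points[i, ] - cur
    len <- sqrt(sum(seg^2))
    if (len >= spacing - 1e-12) {
      cur <- cur + seg / len * spacing
      out <- rbind(out, cur)
    } else {
      i <- i + 1L
    }
  }
  unname(out)
}

#' Export a configuration as an XYZ frame
#'
#' @param fibril a `fibril` object.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(fibril, path, comment = "fibrilmd configuration") {
  pos <- fibril$system$pos
  role <- fibril$system$role
  sym <- c(helical = "C", telopeptide = "N", extension = "O", clamp = "S")[role]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(pos)), comment), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", sym, pos[, 1], pos[, 2], pos[, 3]), con)
  invisible(path)
}

#' Export the system as a LAMMPS data file
#'
#' Writes atoms (molecular style), typed bonds and angles. Bond types
#' follow [BOND_SPECIES]; each angle gets its own type so that per-angle
#' equilibrium values survive the export. Intended for cross-checking the
#' model in an external engine.
#'
#' @param fibril a `fibril` object.
#' @param ff force field (for masses and coefficient comments).
#' @param path output path.
#' @export
write_lammps_data <- function(fibril, ff, path) {
  sys <- fibril$system; topo <- fibril$topology
  n <- nrow(sys$pos)
  b <- topo$bonds; a <- topo$angles
  btype <- match(b$species, BOND_SPECIES)
  pad <- 100
  lims <- rbind(range(sys$pos[, 1]), range(sys$pos[, 2]), range(sys$pos[, 3]))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("fibrilmd coarse-grained collagen fibril data file")
  w("")
  w("%d atoms", n); w("%d bonds", nrow(b)); w("%d angles", nrow(a))
  w("")
  w("1 atom types"); w("%d bond types", length(BOND_SPECIES))
  w("%d angle types", nrow(a))
  w("")
  w("%.4f %.4f xlo xhi", lims[1, 1] - pad, lims[1, 2] + pad)
  w("%.4f %.4f ylo yhi", lims[2, 1] - pad, lims[2, 2] + pad)
  w("%.4f %.4f zlo zhi", lims[3, 1] - pad, lims[3, 2] + pad)
  w("")
  w("Masses"); w("")
  w("1 %.4f", ff$mass)
  w("")
  w("Atoms # molecular"); w("")
  writeLines(sprintf("%d %d 1 %.6f %.6f %.6f", seq_len(n), sys$molecule,
                     sys$pos[, 1], sys$pos[, 2], sys$pos[, 3]), con)
  if (nrow(b) > 0) {
    w(""); w("Bonds"); w("")
    writeLines(sprintf("%d %d %d %d", seq_len(nrow(b)), btype, b$i, b$j), con)
  }
  if (nrow(a) > 0) {
    w(""); w("Angles"); w("")
    writeLines(sprintf("%d %d %d %d %d", seq_len(nrow(a)), seq_len(nrow(a)),
                       a$i, a$j, a$k), con)
  }
  invisible(path)
}
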