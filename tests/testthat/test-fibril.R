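# Fibril geometry: molecules, cross-section mesh, staggered assembly,
# fixtures, exports, and the optional reference-structure reader.

test_that("build_molecule places beads exactly r0 apart with angles in range", {
  spec <- fibril_spec(seed = 7)
  set.seed(7)
  bm <- build_molecule(spec)
  d <- sqrt(rowSums(diff(bm$pos)^2))
  expect_equal(d, rep(spec$r0, length(d)), tolerance = 1e-12)
  expect_equal(bm$n_helical, 218L)
  expect_equal(sum(bm$zone != "extension"), 218L)
  expect_equal(sum(bm$zone == "extension"), 80L)
  phi <- fibrilmd:::triplet_angles(bm$pos)
  expect_true(all(phi >= 170 - 1e-9 & phi <= 180 + 1e-9))
  expect_lt(min(phi), 172)   # waviness actually exercises the range
  # contour length of the full chain
  expect_equal(sum(d), (nrow(bm$pos) - 1) * spec$r0, tolerance = 1e-9)
})

test_that("zero waviness gives a perfectly straight chain", {
  spec <- fibril_spec(waviness_deg = 0, n_extension = 0)
  set.seed(1)
  bm <- build_molecule(spec)
  expect_true(all(abs(bm$pos[, 2:3]) < 1e-12))
  phi <- fibrilmd:::triplet_angles(bm$pos)
  expect_equal(phi, rep(180, length(phi)), tolerance = 1e-9)
})

test_that("excessive waviness is rejected with the offending triplet", {
  spec <- fibril_spec(seed = 3)
  spec$waviness_deg <- 30   # beyond the validated range, forced by hand
  set.seed(3)
  expect_error(build_molecule(spec), "triplet")
})

test_that("cross-section mesh matches brute-force lattice enumeration", {
  s <- 15.45
  m <- mesh_cross_section(2.1 * s, s)
  expect_equal(nrow(m), 7L)   # hexagon + centre
  # brute-force oracle: enumerate a large triangular lattice and filter
  oracle <- function(diameter, spacing) {
    pts <- expand.grid(j = -30:30, k = -30:30)
    y <- (pts$k + (pts$j %% 2) / 2) * spacing
    z <- pts$j * spacing * sqrt(3) / 2
    sum(y^2 + z^2 <= (diameter / 2)^2 + 1e-9)
  }
  for (d in c(2.1 * s, 4 * s, 6.3 * s)) {
    expect_equal(nrow(mesh_cross_section(d, s)), oracle(d, s))
  }
  full <- mesh_cross_section(202, 15.45)
  expect_gte(nrow(full), 150)
  expect_lte(nrow(full), 160)
  # minimum spacing is the lattice constant
  dm <- as.matrix(stats::dist(m))
  expect_gte(min(dm[dm > 0]), s - 1e-9)
})

test_that("assembled fibril reproduces the D-banding and gap geometry", {
  fib <- cached_mini()
  spec <- fib$spec
  expect_equal(measure_banding(fib), spec$d_period)
  # bead count: per line, molecules_per_line chains plus one extension at
  # each line end
  n_lines <- fib$n_molecules / spec$molecules_per_line
  expect_equal(nrow(fib$system$pos),
               n_lines * (spec$molecules_per_line * spec$n_beads +
                            2 * spec$n_extension))
  # telopeptide flag covers exactly 4 beads at each molecule end
  tp <- table(fib$system$molecule[fib$system$role == "telopeptide"])
  expect_true(all(tp == 8))
  # two rigid clamp groups of 10 beads per captured chain end
  expect_equal(sum(fib$system$clamp_group == 1L) %% spec$n_clamp, 0L)
  expect_equal(sum(fib$system$clamp_group == 2L) %% spec$n_clamp, 0L)
  # no overlapping beads in the initial configuration
  close <- fibrilmd:::cg_close_pairs(fib$system$pos, 0.5 * spec$r0)
  expect_equal(nrow(close), 0L)
  # extension beads: 40 at each end of every line
  ext_per_mol <- table(fib$system$molecule[fib$system$role %in%
                                             c("extension", "clamp")])
  expect_true(all(ext_per_mol == 2 * spec$n_extension /
                    spec$molecules_per_line))
  expect_equal(sum(fib$system$role %in% c("extension", "clamp")),
               n_lines * 2 * spec$n_extension)
})

test_that("gap zones measure 0.6 D along lines with several molecules", {
  spec <- fibril_spec(diameter = 2.1 * 15.45, lattice_spacing = 15.45,
                      molecules_per_line = 2, waviness_deg = 0, seed = 2)
  fib <- build_fibril(spec)
  gaps <- measure_line_gaps(fib)
  expect_equal(length(gaps), 7L)
  expect_equal(gaps, rep(0.6 * spec$d_period, 7), tolerance = 1e-9)
})

test_that("rebuilding with the same seed is bit-identical", {
  a <- build_fibril(fibril_spec(diameter = 2.1 * 15.45, lattice_spacing = 15.45,
                                seed = 11))
  b <- build_fibril(fibril_spec(diameter = 2.1 * 15.45, lattice_spacing = 15.45,
                                seed = 11))
  expect_identical(a$system$pos, b$system$pos)
  expect_identical(a$topology, b$topology)
})

test_that("fixtures have the advertised minimal structure", {
  d <- make_fixture("dimer", FF)
  expect_equal(nrow(d$system$pos), 2L)
  expect_equal(nrow(d$topology$bonds), 1L)
  expect_equal(sqrt(sum(diff(d$system$pos)^2)), FF$bonds$backbone$r0)
  ad <- make_fixture("dimer", FF, species = "age")
  expect_equal(sqrt(sum(diff(ad$system$pos)^2)), FF$bonds$age$r0)
  tr <- make_fixture("angle_triplet", FF, phi = 174)
  expect_equal(fibrilmd:::triplet_angles(tr$system$pos), 174, tolerance = 1e-9)
  mini <- cached_mini()
  # closed form: 7 lines x (218 beads + 2 x 40 extensions)
  expect_equal(nrow(mini$system$pos), 7 * (218 + 80))
  expect_equal(mini$n_molecules, 7L)
  expect_error(make_fixture("nonsense"), "arg")
})

test_that("reference-structure reader falls back and round-trips a line", {
  expect_message(out <- read_reference_structure("no/such/file.pdb"),
                 "falling back")
  expect_null(out)
  # straight-line control points resampled at r0 reproduce the straight chain
  pts <- cbind(seq(0, 500, by = 2.5), 0, 0)
  beads <- resample_curve(pts, 14.0)
  expect_equal(diff(beads[, 1]), rep(14, nrow(beads) - 1), tolerance = 1e-9)
  spec <- fibril_spec(waviness_deg = 0, n_extension = 0, n_beads = 36)
  set.seed(1)
  bm <- build_molecule(spec)
  expect_equal(beads[1:36, ], unname(bm$pos), tolerance = 1e-9)
})

test_that("PDB-format reference chains parse into smoothed control points", {
  skip_if_not_installed("bio3d")
  # synthetic straight-chain PDB fixture, written on the fly
  tf <- tempfile(fileext = ".pdb")
  n <- 60
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    1:n, 1:n, seq(0, by = 3.1, length.out = n), 0, 0)
  writeLines(c(lines, "END"), tf)
  cps <- read_reference_structure(tf)
  expect_equal(length(cps), 1L)
  expect_equal(nrow(cps[[1]]), n)
  expect_lt(max(abs(cps[[1]][, 2:3])), 1e-6)
  beads <- resample_curve(cps[[1]], 14.0)
  expect_equal(diff(beads[, 1]), rep(14, nrow(beads) - 1), tolerance = 1e-6)
})

test_that("geometry exports write well-formed files", {
  fib <- make_fixture("two_molecule", FF)
  xyz <- tempfile(fileext = ".xyz")
  write_xyz(fib, xyz)
  ln <- readLines(xyz)
  expect_equal(as.integer(ln[1]), nrow(fib$system$pos))
  expect_equal(length(ln), nrow(fib$system$pos) + 2L)
  dat <- tempfile(fileext = ".data")
  write_lammps_data(fib, FF, dat)
  ln <- readLines(dat)
  expect_true(any(grepl("^60 atoms$", ln)))
  expect_true(any(grepl("^58 bonds$", ln)))
  expect_true(any(grepl("Angles", ln)))
})
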