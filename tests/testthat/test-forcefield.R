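# Interaction laws: trilinear breakable bonds, harmonic angles, soft-core
# Lennard-Jones pairs.

test_that("trilinear bond force reproduces the tabulated backbone values", {
  law <- FF$bonds$backbone
  expect_equal(bond_force(14.0, law), 0)
  # first-branch value at the hyperelastic onset: k0 * (r1 - r0)
  expect_equal(bond_force(18.20, law), 17.13 * (18.20 - 14.00), tolerance = 1e-12)
  # peak tension at the breaking distance: k0*(r1-r0) + k1*(r_break-r1)
  expect_equal(bond_force(21.00, law), 17.13 * 4.20 + 97.66 * 2.80,
               tolerance = 1e-12)
  expect_equal(bond_force(21.00, law), 345.394, tolerance = 1e-6)
  # identically zero beyond the regularization ramp, for every species
  for (sp in names(FF$bonds)) {
    l <- FF$bonds[[sp]]
    expect_identical(bond_force(l$r_break + l$a + c(0, 0.5, 10, 1e4), l),
                     rep(0, 4))
  }
  expect_error(bond_force(c(15, NaN), law), "non-finite")
  expect_error(bond_force(-1, law), "positive")
})

test_that("bond force is continuous across all branch boundaries", {
  h <- 1e-4
  for (sp in names(FF$bonds)) {
    l <- FF$bonds[[sp]]
    for (rb in c(l$r1, l$r_break, l$r_break + l$a)) {
      jump <- abs(bond_force(rb + h, l) - bond_force(rb - h, l))
      # the jump over a 2e-4 A step must be slope-limited, far below the peak
      expect_lt(jump, 1e-8 * l$t_peak + 2 * h * max(l$k0, l$k1, l$t_peak / l$a))
    }
    # direct continuity at the boundary points themselves
    grid <- sort(c(seq(l$r0 * 0.5, l$r_break + l$a + 2, length.out = 2000),
                   l$r1, l$r_break, l$r_break + l$a))
    f <- bond_force(grid, l)
    expect_true(all(is.finite(f)))
  }
})

test_that("bond energy is the antiderivative of minus the force", {
  for (sp in c("backbone", "age", "ecl_divalent", "ecl_trivalent", "extension")) {
    l <- FF$bonds[[sp]]
    h <- 1e-6
    r <- seq(l$r0 + 1e-3, l$r_break + l$a - 1e-3, length.out = 500)
    # keep clear of the branch points where the derivative is one-sided
    near <- outer(r, c(l$r1, l$r_break), function(a, b) abs(a - b) < 10 * h)
    r <- r[!apply(near, 1, any)]
    dnum <- (bond_energy(r + h, l) - bond_energy(r - h, l)) / (2 * h)
    expect_equal(dnum, bond_force(r, l), tolerance = 1e-6)
    expect_equal(bond_energy(l$r0, l), 0)
    # plateau beyond rupture equals the total work to rupture
    expect_equal(bond_energy(l$r_break + l$a + 50, l), law_work(l),
                 tolerance = 1e-10)
    expect_equal(bond_energy(1e6, l), bond_energy(l$r_break + l$a, l))
  }
})

test_that("peak-force ordering and rupture distances match the bond-law table", {
  peaks <- vapply(FF$bonds, function(l) l$t_peak, numeric(1))
  expect_gt(peaks[["backbone"]], peaks[["ecl_trivalent"]])
  expect_gt(peaks[["ecl_trivalent"]], peaks[["ecl_divalent"]])
  # among the physical species (backbone and cross-links; the reinforced
  # extension is an artificial clamp-region species) the AGE law has the
  # largest rupture distance
  rb <- vapply(FF$bonds[c("backbone", "ecl_divalent", "ecl_trivalent", "age")],
               function(l) l$r_break, numeric(1))
  expect_equal(unname(rb[["age"]]), 31.72)
  expect_equal(names(which.max(rb)), "age")
})

test_that("angle law is harmonic about the per-triplet equilibrium", {
  law <- FF$angle
  expect_equal(angle_moment(175, law, phi0_deg = 175), 0)
  d <- 3
  expect_equal(angle_energy(175 + d, law, 175), angle_energy(175 - d, law, 175))
  # moment 2*k*dphi at dphi = 0.1 rad under the default convention
  phi0 <- 175
  phi <- phi0 + 0.1 * 180 / pi
  expect_equal(angle_moment(phi, law, phi0), 2 * 14.98 * 0.1, tolerance = 1e-9)
  half <- angle_law(14.98, convention = "half")
  expect_equal(angle_moment(phi, half, phi0), 14.98 * 0.1, tolerance = 1e-9)
  expect_error(angle_moment(-5, law), "0, 360")
})

test_that("soft-core Lennard-Jones pair law matches its defining points", {
  pl <- FF$pair
  # bare potential crosses zero exactly at sigma
  expect_equal(pair_energy(14.72, pl, shifted = FALSE), 0, tolerance = 1e-12)
  # force vanishes at the analytic minimum 2^(1/6) sigma
  expect_equal(pair_force(2^(1 / 6) * 14.72, pl), 0, tolerance = 1e-9)
  # soft core: constant force below lambda*sigma = 13.248 A
  expect_equal(pair_force(13.0, pl), pair_force(0.9 * 14.72, pl))
  expect_equal(pair_force(5, pl), pair_force(13.248, pl), tolerance = 1e-9)
  # truncation: energy and force zero at/beyond the cutoff
  expect_equal(pair_energy(pl$cutoff, pl), 0, tolerance = 1e-12)
  expect_identical(pair_force(pl$cutoff + c(0.01, 5), pl), c(0, 0))
  expect_error(pair_force(0, pl), "positive")
  # energy-force consistency in the smooth region
  h <- 1e-6
  r <- seq(pl$r_soft + 0.01, pl$cutoff - 0.01, length.out = 300)
  dnum <- -(pair_energy(r + h, pl) - pair_energy(r - h, pl)) / (2 * h)
  expect_equal(dnum, pair_force(r, pl), tolerance = 1e-6)
})

test_that("bond_law validates its invariants", {
  expect_error(bond_law("x", 14, 13, 21, 1, 1), "r0 < r1")
  expect_error(bond_law("x", 14, 18, 17, 1, 1), "r0 < r1")
  expect_error(bond_law("x", 14, 18, 21, -1, 1), "positive")
  expect_error(bond_law("x", 14, 18, 21, 1, 1, z = 1.5), "z must")
  l <- bond_law("x", 14, 18, 21, 1, 2, z = 0.1)
  expect_equal(l$a, 0.1 * (21 - 18))
})

test_that("total energy decomposes exactly and matches brute-force summation", {
  dimer <- make_fixture("dimer", FF)
  e <- total_energy(dimer$system, dimer$topology, FF)
  expect_equal(e$e_total, 0)
  fib <- cached_mini()
  ec <- total_energy(fib$system, fib$topology, FF, method = "cell")
  eb <- total_energy(fib$system, fib$topology, FF, method = "brute")
  expect_equal(ec$e_total, ec$e_bond + ec$e_angle + ec$e_inter)
  expect_equal(ec$e_total, eb$e_total, tolerance = 1e-12)
  # dangling indices rejected
  bad <- fib$topology
  bad$bonds$j[1] <- nrow(fib$system$pos) + 5L
  expect_error(total_energy(fib$system, bad, FF), "outside")
})

test_that("internal forces obey Newton's third law on the assembled fibril", {
  fib <- cached_mini()
  fr <- compute_forces(fib$system, fib$topology, FF)
  fmax <- max(abs(fr$forces))
  expect_lt(max(abs(colSums(fr$forces))), 1e-10 * fmax)
})

test_that("neighbour-list forces equal the O(N^2) reference", {
  fib <- cached_mini()
  fc <- compute_forces(fib$system, fib$topology, FF, method = "cell")$forces
  fb <- compute_forces(fib$system, fib$topology, FF, method = "brute")$forces
  expect_lt(max(abs(fc - fb)), 1e-10 * max(abs(fb)))
})
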