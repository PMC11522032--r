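# Dynamics engine: minimization, integration, thermostat, bond breaking,
# and parameter recovery from simulated pulls.

quiet_protocol <- function(...) {
  args <- list(...)
  base <- list(temperature = 0, tau = 0, sample_every = 10)
  do.call(md_protocol, utils::modifyList(base, args))
}

# quasi-static pull of a two-bead fixture; returns force-extension samples
pull_dimer <- function(species, r_to, dt = 2, speed = 5e-3) {
  fib <- make_fixture("dimer", FF, species = species)
  law <- FF$bonds[[species]]
  pr <- md_protocol(temperature = 0, tau = 0, dt_tensile = dt,
                    pull_speed = speed, sample_every = 5,
                    max_strain = (r_to - law$r0) / law$r0,
                    stop_min_strain = 1e9, n_smooth = 5, seed = 1)
  run <- tensile_test(fib, FF, pr)
  data.frame(r = run$L0 * (1 + run$series$strain),
             force = run$series$stress * fib$area)
}

test_that("minimization relaxes a stretched dimer to its equilibrium length", {
  fib <- make_fixture("dimer", FF, r = 15)
  out <- minimize(fib, FF, ftol = 1e-6, fix_clamps = FALSE)
  r <- sqrt(sum(diff(out$system$pos)^2))
  expect_equal(r, FF$bonds$backbone$r0, tolerance = 1e-4)
  info <- attr(out, "minimize_info")
  expect_true(info$converged)
})

test_that("minimization is a descent and leaves minimal fixtures in place", {
  fib <- cached_mini()
  e0 <- total_energy(fib$system, fib$topology, FF)$e_total
  out <- minimize(fib, FF, max_iter_sd = 50, max_iter_cg = 100)
  e1 <- attr(out, "minimize_info")$energy
  expect_lte(e1, e0)
  # an already-minimal dimer does not move beyond tolerance
  dim0 <- make_fixture("dimer", FF)
  out <- minimize(dim0, FF, ftol = 1e-6, fix_clamps = FALSE)
  expect_lt(max(abs(out$system$pos - dim0$system$pos)), 1e-8)
})

test_that("microcanonical energy drift stays below 1e-4 over 1e4 steps", {
  fib <- cached_mini_minimized()
  fib$system$vel <- fibrilmd:::init_velocities(fib, 300, seed = 4)
  pr <- quiet_protocol(sample_every = 100)
  out <- run_md(fib, FF, pr, n_steps = 1e4, dt = 1, clamp_mode = "fixed",
                thermostat = FALSE)
  ser <- out$series
  u <- fibril_units()
  ndof <- 3 * sum(fib$system$clamp_group == 0L)
  ke <- ser$temperature * u$kB * ndof / 2
  etot <- ke + ser$e_bond + ser$e_angle + ser$e_inter
  expect_equal(nrow(out$events), 0L)
  expect_lt(max(abs(etot - etot[1])) / abs(etot[1]), 1e-4)
})

test_that("the thermostat holds the kinetic temperature near its target", {
  fib <- cached_mini_minimized()
  pr <- md_protocol(temperature = 300, tau = 1000, sample_every = 50, seed = 8)
  out <- run_md(fib, FF, pr, n_steps = 4000, dt = 10, clamp_mode = "fixed")
  temp <- out$series$temperature
  burn <- temp[out$series$step > 1000]
  expect_lt(abs(mean(burn) - 300) / 300, 0.05)
})

test_that("total momentum is conserved with thermostat off and clamps free", {
  fib <- cached_mini_minimized()
  fib$system$vel <- fibrilmd:::init_velocities(fib, 100, seed = 6)
  pr <- quiet_protocol(sample_every = 1000)
  out <- run_md(fib, FF, pr, n_steps = 1000, dt = 5, clamp_mode = "free",
                thermostat = FALSE)
  m <- fib$system$mass
  p0 <- colSums(fib$system$vel * m)
  p1 <- colSums(out$fibril$system$vel * m)
  scale <- sum(m * sqrt(rowSums(fib$system$vel^2)))
  expect_lt(max(abs(p1 - p0)) / scale, 1e-10)
})

test_that("a dimer at equilibrium with zero velocities stays at rest", {
  # (an angle triplet is not force-free: its 1-3 pair interacts)
  for (sp in c("backbone", "age")) {
    fib <- make_fixture("dimer", FF, species = sp)
    pr <- quiet_protocol()
    out <- run_md(fib, FF, pr, n_steps = 200, dt = 5, clamp_mode = "free",
                  thermostat = FALSE)
    expect_lt(max(abs(out$fibril$system$pos - fib$system$pos)), 1e-9)
  }
})

test_that("a dimer stretched past rupture breaks exactly once and unloads", {
  law <- FF$bonds$backbone
  curve <- pull_dimer("backbone", law$r_break + law$a + 1.5)
  # exactly one rupture: force identically zero beyond r_break + a
  beyond <- curve$force[curve$r > law$r_break + law$a + 0.05]
  expect_true(length(beyond) > 3)
  expect_true(all(beyond == 0))
  # intact up to the peak, matching the law within 2%
  inside <- curve[curve$r > law$r0 + 0.5 & curve$r < law$r_break - 0.1, ]
  expect_equal(inside$force, bond_force(inside$r, law),
               tolerance = 0.02)
})

test_that("a quasi-static single-bond pull recovers the tabulated stiffnesses", {
  law <- FF$bonds$age
  curve <- pull_dimer("age", law$r_break - 0.3)
  seg1 <- curve[curve$r > law$r0 + 0.3 & curve$r < law$r1 - 0.3, ]
  seg2 <- curve[curve$r > law$r1 + 0.3 & curve$r < law$r_break - 0.5, ]
  k0_hat <- stats::coef(stats::lm(force ~ r, seg1))[2]
  k1_hat <- stats::coef(stats::lm(force ~ r, seg2))[2]
  expect_equal(unname(k0_hat), law$k0, tolerance = 0.05)
  expect_equal(unname(k1_hat), law$k1, tolerance = 0.05)
})

test_that("detect_breaks flags softening bonds and never un-breaks", {
  fib <- make_fixture("dimer", FF, r = 21.05)  # past r_break, inside the ramp
  out <- detect_breaks(fib, FF)
  ev <- attr(out, "break_events")
  expect_equal(nrow(ev), 1L)
  expect_equal(out$topology$bonds$state, 1L)
  expect_gte(ev$r, FF$bonds$backbone$r_break)
  # past the ramp: severed
  out$system$pos[2, 1] <- 36
  out2 <- detect_breaks(out, FF)
  expect_equal(out2$topology$bonds$state, 2L)
  # unchanged below the threshold
  ok <- detect_breaks(make_fixture("dimer", FF, r = 20), FF)
  expect_equal(ok$topology$bonds$state, 0L)
  expect_equal(nrow(attr(ok, "break_events")), 0L)
})

test_that("re-running with the same seed is bit-identical", {
  fib <- cached_mini_minimized()
  pr <- md_protocol(sample_every = 100, seed = 12)
  a <- run_md(fib, FF, pr, n_steps = 500, dt = 10, clamp_mode = "fixed")
  b <- run_md(fib, FF, pr, n_steps = 500, dt = 10, clamp_mode = "fixed")
  expect_identical(a$fibril$system$pos, b$fibril$system$pos)
  expect_identical(a$series, b$series)
})

test_that("zero pulling speed keeps strain at zero and stress fluctuating about zero", {
  fib <- cached_mini_minimized()
  pr <- md_protocol(pull_speed = 0, sample_every = 50, seed = 3)
  run <- tensile_test(fib, FF, pr, n_steps = 1500)
  expect_lt(max(abs(run$series$strain)), 1e-9)
  # only the small residual assembly pre-tension remains, far below the
  # stress scale of an actual pull
  expect_lt(stats::median(run$series$stress), 0.03)
})

test_that("the staged protocol rejects out-of-order cross-linking", {
  fib <- cached_mini()
  cfg <- crosslink_config(n_age = 1)
  expect_error(insert_ages(fib, cfg, strict = TRUE), "before equilibration")
  fib2 <- fib
  attr(fib2, "equilibrated") <- TRUE
  expect_no_error(insert_ages(fib2, cfg, strict = TRUE))
})
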