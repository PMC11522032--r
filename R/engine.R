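# Simulation protocol: minimization, Langevin equilibration, and the
# displacement-controlled tensile test with rigid end clamps.

#' Simulation protocol settings
#'
#' Defaults mirror the published protocol (300 K NVT, 10 fs equilibration
#' timestep, 1 fs tensile timestep, 1e-4 A/fs = 10 m/s pulling speed);
#' the desk-scale presets override the step counts, tensile timestep and
#' pulling speed (see [fibril_preset()]).
#'
#' @param temperature thermostat temperature (K).
#' @param dt_equil,dt_tensile timesteps (fs).
#' @param equil_steps,post_equil_steps equilibration steps before and after
#'   cross-link insertion.
#' @param pull_speed relative clamp separation speed (A/fs); each clamp
#'   moves at half this speed.
#' @param tau Langevin damping time (fs); applied to non-clamp beads only.
#' @param skin neighbour-list skin (A).
#' @param sample_every record a sample every this many steps.
#' @param stop_frac terminate the pull when the smoothed stress falls below
#'   this fraction of its running peak...
#' @param stop_min_strain ...but not before this strain.
#' @param max_strain hard strain cap for the pull.
#' @param n_smooth samples in the trailing window used for the stopping rule.
#' @param ftol force-norm tolerance of the minimizer (kcal/mol/A).
#' @param seed seed for initial velocities and the thermostat noise.
#' @param deterministic kept in run manifests; all dynamics in this package
#'   are single-threaded and bit-reproducible under a fixed seed.
#' @return an object of class `md_protocol`.
#' @export
md_protocol <- function(temperature = 300, dt_equil = 10, dt_tensile = 1,
                        equil_steps = 4000, post_equil_steps = 3000,
                        pull_speed = 1e-4, tau = 1000, skin = 4,
                        sample_every = 200, stop_frac = 0.05,
                        stop_min_strain = 0.1, max_strain = 0.5,
                        n_smooth = 15, ftol = 1e-3, seed = 1L,
                        deterministic = TRUE) {
  stopifnot(dt_equil > 0, dt_tensile > 0, pull_speed >= 0, temperature >= 0,
            equil_steps >= 0, post_equil_steps >= 0, max_strain > 0)
  structure(as.list(environment()), class = "md_protocol")
}

# Draw Maxwell-Boltzmann velocities for the free beads (zero for clamps),
# removing the net momentum of the free set.
init_velocities <- function(fibril, temperature, seed) {
  set.seed(seed)
  sys <- fibril$system
  n <- nrow(sys$pos)
  u <- fibril_units()
  vth <- sqrt(u$kB * temperature / (sys$mass * u$mv2e))
  vel <- matrix(stats::rnorm(3 * n), n, 3) * vth
  free <- sys$clamp_group == 0L
  if (any(free)) {
    for (d in 1:3) vel[free, d] <- vel[free, d] - mean(vel[free, d])
  }
  vel[!free, ] <- 0
  vel
}

engine_args <- function(fibril, ff) {
  ct <- compiled_topology(fibril$system, fibril$topology, ff)
  is_tc <- as.integer(fibril$topology$bonds$species == "backbone")
  c(ct, list(is_tc = is_tc, laws = ff_law_matrix(ff),
             k_bend = ff$angle$k_bend, angle_factor = ff$angle$factor,
             eps = ff$pair$epsilon, sigma = ff$pair$sigma,
             lambda = ff$pair$lambda, cutoff = ff$pair$cutoff))
}

#' Energy minimization
#'
#' Steepest descent followed by Polak-Ribiere conjugate gradient, stopping
#' on a force-norm tolerance or iteration cap. Clamp beads are held fixed
#' (so the clamp groups keep their relative distance) unless
#' `fix_clamps = FALSE`.
#'
#' @param fibril a `fibril` object.
#' @param ff force field.
#' @param ftol maximum residual force per bead component (kcal/mol/A).
#' @param max_iter_sd,max_iter_cg iteration caps for the two stages.
#' @param fix_clamps hold clamp beads fixed.
#' @return the fibril with relaxed coordinates;
#'   `attr(, "minimize_info")` holds energy, residual force and iteration
#'   counts.
#' @export
minimize <- function(fibril, ff = default_forcefield(), ftol = NULL,
                     max_iter_sd = 200, max_iter_cg = 2000,
                     fix_clamps = TRUE) {
  if (is.null(ftol)) ftol <- 1e-3
  ea <- engine_args(fibril, ff)
  fixed <- if (fix_clamps) as.integer(fibril$system$clamp_group > 0L)
           else integer(nrow(fibril$system$pos))
  res <- cg_minimize(fibril$system$pos, fixed,
                     ea$bond_i, ea$bond_j, ea$bond_species, ea$bond_state,
                     ea$laws, ea$angle_i, ea$angle_j, ea$angle_k,
                     ea$angle_phi0, ea$k_bend, ea$angle_factor,
                     ea$eps, ea$sigma, ea$lambda, ea$cutoff,
                     skin = 2.0, ftol = ftol,
                     max_iter_sd = max_iter_sd, max_iter_cg = max_iter_cg)
  if (!is.finite(res$energy)) stop("minimization produced a non-finite energy")
  fibril$system$pos <- res$pos
  attr(fibril, "minimize_info") <- res[c("energy", "fmax", "iter_sd",
                                         "iter_cg", "converged")]
  fibril
}

run_engine <- function(fibril, ff, protocol, n_steps, dt, clamp_mode,
                       pull_speed = 0, tau = protocol$tau,
                       temperature = protocol$temperature,
                       sample_every = protocol$sample_every,
                       L0 = -1, seed = protocol$seed) {
  ea <- engine_args(fibril, ff)
  cg_run(fibril$system$pos, fibril$system$vel, fibril$system$mass,
         as.integer(fibril$system$clamp_group),
         as.integer(fibril$system$molecule - 1L),
         ea$bond_i, ea$bond_j, ea$bond_species, ea$bond_state, ea$is_tc,
         ea$laws, ea$angle_i, ea$angle_j, ea$angle_k, ea$angle_phi0,
         ea$k_bend, ea$angle_factor, ea$eps, ea$sigma, ea$lambda, ea$cutoff,
         skin = protocol$skin, dt = dt, n_steps = as.integer(n_steps),
         temperature = temperature, tau = tau, pull_speed = pull_speed,
         clamp_mode = as.integer(clamp_mode),
         sample_every = as.integer(sample_every), area = fibril$area,
         L0 = L0, stop_frac = protocol$stop_frac,
         stop_min_strain = protocol$stop_min_strain,
         max_strain = protocol$max_strain, n_smooth = protocol$n_smooth,
         seed = as.integer(seed))
}

assemble_series <- function(res) {
  ser <- as.data.frame(res$series)
  fm <- res$mean_force; ni <- res$n_intact
  for (k in seq_along(BOND_SPECIES)) {
    ser[[paste0("f_", BOND_SPECIES[k])]] <- fm[[k]]
    ser[[paste0("n_", BOND_SPECIES[k])]] <- ni[[k]]
  }
  ser
}

apply_state <- function(fibril, res) {
  fibril$system$pos <- res$pos
  fibril$system$vel <- res$vel
  fibril$topology$bonds$state <- res$bond_state
  fibril
}

#' Integrate the equations of motion
#'
#' Velocity-Verlet with an optional Langevin thermostat. Clamp beads are
#' held fixed (`clamp_mode = "fixed"`), pulled apart (`"pull"`), or
#' integrated freely (`"free"`). With `thermostat = FALSE` the run is
#' microcanonical.
#'
#' @param fibril a `fibril` object (velocities are initialized from a
#'   Maxwell-Boltzmann draw if currently all zero and a thermostat is on).
#' @param ff force field.
#' @param protocol an [md_protocol()].
#' @param n_steps number of steps.
#' @param dt timestep (fs); defaults to the protocol equilibration step.
#' @param clamp_mode `"fixed"`, `"pull"` or `"free"`.
#' @param thermostat logical.
#' @return list with the updated `fibril`, the sampled `series`
#'   data frame, and the break `events`.
#' @export
run_md <- function(fibril, ff = default_forcefield(), protocol = md_protocol(),
                   n_steps, dt = protocol$dt_equil,
                   clamp_mode = c("fixed", "pull", "free"),
                   thermostat = TRUE) {
  clamp_mode <- match.arg(clamp_mode)
  mode <- c(free = 0L, fixed = 1L, pull = 2L)[[clamp_mode]]
  if (thermostat && all(fibril$system$vel == 0)) {
    fibril$system$vel <- init_velocities(fibril, protocol$temperature,
                                         protocol$seed)
  }
  res <- run_engine(fibril, ff, protocol, n_steps, dt, mode,
                    pull_speed = if (mode == 2L) protocol$pull_speed else 0,
                    tau = if (thermostat) protocol$tau else 0)
  list(fibril = apply_state(fibril, res), series = assemble_series(res),
       events = as.data.frame(res$events), L0 = res$L0,
       stopped_early = res$stopped_early)
}

#' Flag newly broken bonds at the current configuration
#'
#' A bond is flagged broken at the first crossing of its species'
#' breaking distance and removed from force evaluation once past
#' `r_break + a`; broken bonds never re-form. The same bookkeeping runs
#' inside the dynamics loop; this operation applies it to a static
#' configuration.
#'
#' @param fibril a `fibril` object.
#' @param ff force field.
#' @return the fibril with updated bond states; `attr(, "break_events")`
#'   lists the new events (bond, species, separation).
#' @export
detect_breaks <- function(fibril, ff = default_forcefield()) {
  b <- fibril$topology$bonds
  pos <- fibril$system$pos
  r <- sqrt(rowSums((pos[b$j, , drop = FALSE] - pos[b$i, , drop = FALSE])^2))
  laws <- ff$bonds[b$species]
  rb <- vapply(laws, `[[`, numeric(1), "r_break")
  ra <- rb + vapply(laws, `[[`, numeric(1), "a")
  new1 <- b$state == 0L & r >= rb
  fibril$topology$bonds$state[new1] <- 1L
  sev <- fibril$topology$bonds$state >= 1L & r >= ra
  fibril$topology$bonds$state[sev] <- 2L
  attr(fibril, "break_events") <- data.frame(
    bond = which(new1), species = b$species[new1], r = r[new1],
    stringsAsFactors = FALSE)
  fibril
}

#' Equilibrate the fibril
#'
#' NVT Langevin run with the clamps held fixed. Marks the fibril as
#' equilibrated, which gates cross-link insertion in [run_protocol()].
#'
#' @inheritParams run_md
#' @param n_steps steps; defaults to `protocol$equil_steps`.
#' @export
equilibrate <- function(fibril, ff = default_forcefield(),
                        protocol = md_protocol(),
                        n_steps = protocol$equil_steps) {
  out <- run_md(fibril, ff, protocol, n_steps = n_steps,
                dt = protocol$dt_equil, clamp_mode = "fixed",
                thermostat = TRUE)
  fib <- out$fibril
  attr(fib, "equilibrated") <- TRUE
  attr(fib, "equil_series") <- out$series
  fib
}

#' Displacement-controlled tensile test
#'
#' Moves the two rigid clamps apart along the fibril axis at the protocol
#' pulling speed, recording strain (clamp separation change over the
#' baseline separation), engineering stress (mean of the two clamp force
#' magnitudes over the construction cross-section area), per-species mean
#' bond forces, intact-bond counts, the mean intra-molecular bond strain
#' and all rupture events. The run ends when the smoothed stress falls
#' below `stop_frac` of its running peak, or at `max_strain`.
#'
#' @inheritParams run_md
#' @param n_steps step cap; by default computed from `max_strain` and the
#'   pulling speed.
#' @return an object of class `tensile_run`: list with `series`, `events`,
#'   `census0` (bond census at the start of the pull), `fibril` (final
#'   state), `area`, `L0`, `protocol`.
#' @export
tensile_test <- function(fibril, ff = default_forcefield(),
                         protocol = md_protocol(), n_steps = NULL) {
  if (!any(fibril$system$clamp_group == 1L) ||
      !any(fibril$system$clamp_group == 2L)) {
    stop("tensile_test needs two clamp groups")
  }
  sep0 <- clamp_separation(fibril)
  if (is.null(n_steps)) {
    if (protocol$pull_speed <= 0) stop("protocol pull_speed must be > 0 (or give n_steps)")
    n_steps <- ceiling(1.05 * protocol$max_strain * sep0 /
                       (protocol$pull_speed * protocol$dt_tensile))
  }
  if (all(fibril$system$vel == 0)) {
    fibril$system$vel <- init_velocities(fibril, protocol$temperature,
                                         protocol$seed)
  }
  census0 <- crosslink_census(fibril)
  res <- run_engine(fibril, ff, protocol, n_steps, protocol$dt_tensile,
                    clamp_mode = 2L, pull_speed = protocol$pull_speed,
                    L0 = sep0)
  structure(list(series = assemble_series(res),
                 events = as.data.frame(res$events),
                 census0 = census0, fibril = apply_state(fibril, res),
                 area = fibril$area, L0 = res$L0, protocol = protocol,
                 stopped_early = res$stopped_early),
            class = "tensile_run")
}

#' @export
print.tensile_run <- function(x, ...) {
  cat(sprintf("<tensile_run> %d samples to strain %.3f | peak stress %.4g kcal/mol/A^3 | %d break events%s\n",
              nrow(x$series), max(x$series$strain), max(x$series$stress),
              nrow(x$events),
              if (isTRUE(x$stopped_early)) " | stress-drop stop" else ""))
  invisible(x)
}

#' Axial separation of the two clamp centroids
#' @param fibril a `fibril` object.
#' @export
clamp_separation <- function(fibril) {
  g <- fibril$system$clamp_group
  mean(fibril$system$pos[g == 2L, 1]) - mean(fibril$system$pos[g == 1L, 1])
}

#' Run the full simulation protocol
#'
#' Build, minimize, equilibrate, insert cross-links, re-equilibrate, and
#' pull: the staged pipeline of a single in-silico tensile experiment.
#' Cross-link insertion is only reached after the first equilibration
#' (attempting to reorder the stages is rejected by the insertion
#' functions).
#'
#' @param spec a [fibril_spec()].
#' @param clconfig a [crosslink_config()].
#' @param protocol an [md_protocol()].
#' @param ff force field.
#' @param verbose print stage progress.
#' @return a `tensile_run` (see [tensile_test()]) with the cross-link
#'   census taken after insertion.
#' @export
run_protocol <- function(spec, clconfig, protocol = md_protocol(),
                         ff = default_forcefield(), verbose = FALSE) {
  stages <- function(name, expr) {
    if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  fib <- stages("build", build_fibril(spec, mass = ff$mass))
  fib <- stages("minimize", minimize(fib, ff, ftol = protocol$ftol))
  fib <- stages("equilibrate", equilibrate(fib, ff, protocol))
  fib <- stages("crosslink", {
    f <- insert_ecl(fib, clconfig, strict = TRUE)
    insert_ages(f, clconfig, strict = TRUE)
  })
  fib <- stages("re-equilibrate",
                equilibrate(fib, ff, protocol,
                            n_steps = protocol$post_equil_steps))
  stages("tensile", tensile_test(fib, ff, protocol))
}
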