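# Shared fixtures and a run cache so expensive tensile simulations are
# computed once per test session and reused across test files.

FF <- default_forcefield()

.run_cache <- new.env(parent = emptyenv())

# Desk-scale tensile run under the mini preset; memoised.
cached_run <- function(n_age, ecl_content = 0, ecl_valence = "divalent",
                       seed = 101L) {
  key <- sprintf("age%g_ecl%g_%s_s%d", n_age, ecl_content, ecl_valence, seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  run <- run_experiment(list(preset = "mini", n_age = n_age,
                             ecl_content = ecl_content,
                             ecl_valence = ecl_valence, seed = seed))
  .run_cache[[key]] <- run
  run
}

cached_mini <- function(seed = 1L) {
  key <- sprintf("mini_s%d", seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  fib <- make_fixture("mini_fibril", FF, seed = seed)
  .run_cache[[key]] <- fib
  fib
}

cached_mini_minimized <- function(seed = 1L) {
  key <- sprintf("minimin_s%d", seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  fib <- minimize(cached_mini(seed), FF, max_iter_sd = 100, max_iter_cg = 500)
  .run_cache[[key]] <- fib
  fib
}

# analytic total work to rupture of a trilinear law
law_work <- function(law) {
  t1 <- law$k0 * (law$r1 - law$r0)
  0.5 * law$k0 * (law$r1 - law$r0)^2 +
    t1 * (law$r_break - law$r1) + 0.5 * law$k1 * (law$r_break - law$r1)^2 +
    0.5 * law$t_peak * law$a
}
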