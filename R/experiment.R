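# Config-driven orchestration: single runs, sweeps over cross-link
# densities, and report regeneration from archived runs.

#' Desk-scale and full-scale presets
#'
#' `"mini"`: 7 lattice sites, one full-length molecule per line (~2,100
#' beads, the staggered molecule ends providing the gap-zone weak
#' planes); short equilibrations, 20 fs tensile timestep and a
#' 2.5e-4 A/fs (25 m/s) pulling speed -- the configuration used by the
#' tests and the acceptance analyses. `"full"`: the published geometry (20.2 nm
#' cross-section, ~155 molecules) and protocol (80 ns equilibration,
#' 10 ns after insertion, 1 fs tensile step at 10 m/s); cluster-scale,
#' not exercised by the tests.
#'
#' @param name `"mini"` or `"full"`.
#' @param seed seed applied to both the spec and the protocol.
#' @return list with `spec` ([fibril_spec()]) and `protocol`
#'   ([md_protocol()]).
#' @export
fibril_preset <- function(name = c("mini", "full"), seed = 1L) {
  name <- match.arg(name)
  if (name == "mini") {
    list(spec = fibril_spec(diameter = 2.1 * 15.45, lattice_spacing = 15.45,
                            molecules_per_line = 1, seed = seed),
         protocol = md_protocol(dt_equil = 10, dt_tensile = 20,
                                equil_steps = 4000, post_equil_steps = 3000,
                                pull_speed = 2.5e-4, tau = 2000,
                                sample_every = 150, max_strain = 0.5,
                                seed = seed))
  } else {
    list(spec = fibril_spec(diameter = 202, lattice_spacing = 15.45,
                            molecules_per_line = 1, seed = seed),
         protocol = md_protocol(dt_equil = 10, dt_tensile = 1,
                                equil_steps = 8e6, post_equil_steps = 1e6,
                                pull_speed = 1e-4, tau = 1000,
                                sample_every = 1000, max_strain = 0.5,
                                seed = seed))
  }
}

validate_config <- function(config) {
  req <- c("preset", "n_age", "ecl_content", "ecl_valence", "seed")
  missing <- setdiff(req, names(config))
  if (length(missing) > 0) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  }
  if (!config$preset %in% c("mini", "full")) {
    stop("config$preset: must be 'mini' or 'full'")
  }
  if (!is.numeric(config$n_age) || config$n_age < 0) {
    stop("config$n_age: must be a non-negative number")
  }
  if (!is.numeric(config$ecl_content) || config$ecl_content < 0 ||
      config$ecl_content > 100) {
    stop("config$ecl_content: must be in [0, 100]")
  }
  if (!config$ecl_valence %in% c("divalent", "trivalent")) {
    stop("config$ecl_valence: must be 'divalent' or 'trivalent'")
  }
  invisible(config)
}

#' Run a single configured experiment
#'
#' Executes the full protocol (build, minimize, equilibrate, cross-link,
#' re-equilibrate, pull) for one configuration and optionally archives the
#' series, events, summary metrics and a reproduction manifest.
#'
#' @param config named list (or path to a YAML file) with fields `preset`
#'   (`"mini"`/`"full"`), `n_age`, `ecl_content`, `ecl_valence`, `seed`,
#'   and optional `spec`/`protocol` overrides (named lists applied over
#'   the preset) and `capture_radius`.
#' @param output_dir archive directory, or `NULL` to skip archiving.
#' @param ff force field.
#' @param verbose print stage progress.
#' @return a `tensile_run` with the summary metrics attached as
#'   `attr(, "metrics")`.
#' @export
run_experiment <- function(config, output_dir = NULL,
                           ff = default_forcefield(), verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  preset <- fibril_preset(config$preset, seed = as.integer(config$seed))
  spec <- preset$spec; protocol <- preset$protocol
  if (!is.null(config$spec)) {
    spec <- do.call(fibril_spec, utils::modifyList(unclass(spec), config$spec))
  }
  if (!is.null(config$protocol)) {
    pr <- utils::modifyList(unclass(protocol), config$protocol)
    protocol <- do.call(md_protocol, pr[setdiff(names(pr), "deterministic")])
  }
  capture <- if (is.null(config$capture_radius)) 28 else config$capture_radius
  clc <- crosslink_config(ecl_content = config$ecl_content,
                          ecl_valence = config$ecl_valence,
                          n_age = config$n_age, capture_radius = capture,
                          seed = as.integer(config$seed))
  run <- run_protocol(spec, clc, protocol, ff, verbose = verbose)
  metrics <- summarize_mechanics(run)
  attr(run, "metrics") <- metrics
  attr(run, "config") <- config
  if (!is.null(output_dir)) archive_run(run, config, output_dir)
  run
}

metrics_as_list <- function(m) {
  out <- m[c("sigma_peak", "strain_at_peak", "w_f", "eps0", "sigma_0",
             "delta_sigma", "failure_strain", "partial")]
  out$sigma_peak_MPa <- stress_to_MPa(m$sigma_peak)
  bf <- m$broken_fractions
  if (!is.null(bf)) out$broken_fractions <- as.list(bf)
  out
}

archive_run <- function(run, config, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$series, file.path(output_dir, "series.csv"),
                   row.names = FALSE)
  utils::write.csv(run$events, file.path(output_dir, "events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(metrics_as_list(attr(run, "metrics")),
                       file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("fibrilmd")),
                   L0 = run$L0, area = run$area,
                   n_beads = nrow(run$fibril$system$pos),
                   n_molecules = run$fibril$n_molecules,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  invisible(output_dir)
}

#' Sweep over cross-link densities and seeds
#'
#' One full protocol run per combination of AGE density, enzymatic
#' content, valence and seed; independent cells are independently seeded
#' and a failed cell is recorded and skipped, not fatal. With an
#' `output_root`, per-cell archives make the sweep resumable (archived
#' cells are not recomputed).
#'
#' @param n_age,ecl_content,ecl_valence vectors defining the grid.
#' @param seeds one or more seeds per cell.
#' @param preset preset name.
#' @param output_root archive root, or `NULL`.
#' @param config_extra extra config fields applied to every cell (e.g.
#'   `protocol` overrides).
#' @param ff force field.
#' @param verbose print per-cell progress.
#' @return long-format data frame with one row per cell (metrics columns
#'   plus `status`).
#' @export
run_sweep <- function(n_age = c(0.5, 40), ecl_content = 0,
                      ecl_valence = "divalent", seeds = 1L,
                      preset = "mini", output_root = NULL,
                      config_extra = NULL, ff = default_forcefield(),
                      verbose = FALSE) {
  grid <- expand.grid(n_age = n_age, ecl_content = ecl_content,
                      ecl_valence = ecl_valence, seed = seeds,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(q) {
    cell <- grid[q, ]
    config <- c(as.list(cell), list(preset = preset))
    if (!is.null(config_extra)) config <- utils::modifyList(config, config_extra)
    cell_dir <- if (is.null(output_root)) NULL else {
      file.path(output_root, sprintf("age%g_ecl%g_%s_seed%d", cell$n_age,
                                     cell$ecl_content, cell$ecl_valence,
                                     cell$seed))
    }
    if (!is.null(cell_dir) && file.exists(file.path(cell_dir, "summary.json"))) {
      m <- jsonlite::read_json(file.path(cell_dir, "summary.json"),
                               simplifyVector = TRUE)
      return(cbind(cell, as.data.frame(m[c("sigma_peak", "w_f", "delta_sigma",
                                           "failure_strain")]),
                   status = "cached"))
    }
    if (verbose) message(sprintf("sweep cell %d/%d: N_AGE=%g ECL=%g%% %s seed=%d",
                                 q, nrow(grid), cell$n_age, cell$ecl_content,
                                 cell$ecl_valence, cell$seed))
    out <- tryCatch({
      run <- run_experiment(config, output_dir = cell_dir, ff = ff)
      m <- attr(run, "metrics")
      cbind(cell, data.frame(sigma_peak = m$sigma_peak, w_f = m$w_f,
                             delta_sigma = m$delta_sigma,
                             failure_strain = m$failure_strain),
            status = "ok")
    }, error = function(e) {
      cbind(cell, data.frame(sigma_peak = NA, w_f = NA, delta_sigma = NA,
                             failure_strain = NA),
            status = paste("failed:", conditionMessage(e)))
    })
    out
  })
  res <- do.call(rbind, rows)
  if (!is.null(output_root)) {
    dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(output_root, "sweep_results.csv"),
                     row.names = FALSE)
  }
  res
}

#' Regenerate figures and tables from archived runs
#'
#' A pure function of the archives: reads every `series.csv` under the
#' root and redraws the stress-strain overlay and, when several cells are
#' present, the metric-versus-density panels. No re-simulation.
#'
#' @param root archive root produced by [run_sweep()] or
#'   [run_experiment()].
#' @param out_dir where to write figures (default: the root).
#' @return character vector of written files (empty, with a message, when
#'   there is nothing to report).
#' @export
report_runs <- function(root, out_dir = root) {
  series_files <- list.files(root, pattern = "^series\\.csv$",
                             recursive = TRUE, full.names = TRUE)
  if (length(series_files) == 0) {
    message("nothing to report under '", root, "'")
    return(invisible(character(0)))
  }
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("report_runs requires ggplot2")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- do.call(rbind, lapply(series_files, function(f) {
    lab <- basename(dirname(f))
    d <- utils::read.csv(f)
    data.frame(cell = lab, strain = d$strain,
               stress = stress_to_MPa(d$stress))
  }))
  written <- character(0)
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = strain, y = stress,
                                            colour = cell)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "global strain", y = "engineering stress (MPa)") +
    ggplot2::theme_minimal()
  f1 <- file.path(out_dir, "stress_strain_overlay.png")
  ggplot2::ggsave(f1, p, width = 7, height = 5, dpi = 150)
  written <- c(written, f1)
  sweep_csv <- file.path(root, "sweep_results.csv")
  if (file.exists(sweep_csv)) {
    sw <- utils::read.csv(sweep_csv)
    sw <- sw[is.finite(sw$sigma_peak), , drop = FALSE]
    if (nrow(sw) > 1) {
      long <- rbind(
        data.frame(n_age = sw$n_age, ecl = sw$ecl_content, value = stress_to_MPa(sw$sigma_peak),
                   metric = "peak stress (MPa)"),
        data.frame(n_age = sw$n_age, ecl = sw$ecl_content, value = stress_to_MPa(sw$w_f),
                   metric = "work to failure (MPa)"),
        data.frame(n_age = sw$n_age, ecl = sw$ecl_content, value = stress_to_MPa(sw$delta_sigma),
                   metric = "delta sigma (MPa)"))
      long <- long[is.finite(long$value), , drop = FALSE]
      p2 <- ggplot2::ggplot(long, ggplot2::aes(x = factor(n_age), y = value,
                                               colour = factor(ecl))) +
        ggplot2::geom_point(size = 2) +
        ggplot2::stat_summary(fun = stats::median, geom = "line",
                              ggplot2::aes(group = factor(ecl))) +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(x = "AGE cross-links per molecule",
                      colour = "ECL content (%)") +
        ggplot2::theme_minimal()
      f2 <- file.path(out_dir, "metrics_vs_density.png")
      ggplot2::ggsave(f2, p2, width = 9, height = 4, dpi = 150)
      written <- c(written, f2)
    }
  }
  invisible(written)
}
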