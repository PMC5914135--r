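#' Run configuration for the analysis pipeline
#'
#' One structured-text (YAML) config per run keeps the whole analysis
#' reproducible; command-line flags override config fields. Defaults
#' generate the noiseless reference dataset: a 15-point concentration
#' series (5e-7 to 3e-5 M), the four solvent-condition kinetic traces and
#' the three species spectra.
#'
#' @param path Optional YAML file; fields present in the file override the
#'   defaults.
#' @return A config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(
    seed = 1729L,
    outdir = ".",
    preset = "znchl",
    noise = list(mult_epsilon = 0, mult_delta_epsilon = 0,
                 add_epsilon = 0, add_delta_epsilon = 0, add_g = 0),
    series = list(n_points = 15L, c_min = 5e-7, c_max = 3e-5),
    kinetics = list(conditions = c("30:70", "20:80", "10:90", "1:99"),
                    t_max = 24, dt = 0.02),
    fit = list(n_starts = 5L, T_K = 293))
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(.usage_error(sprintf("config file not found: %s", path)))
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

.usage_error <- function(msg)
  structure(class = c("jaggpath_usage_error", "error", "condition"),
            list(message = msg, call = NULL))
.data_error <- function(msg)
  structure(class = c("jaggpath_data_error", "error", "condition"),
            list(message = msg, call = NULL))
.nonconvergence_error <- function(msg)
  structure(class = c("jaggpath_nonconvergence_error", "error", "condition"),
            list(message = msg, call = NULL))

.cfg_noise <- function(config) {
  n <- config$noise
  noise_spec(n$mult_epsilon, n$mult_delta_epsilon, n$add_epsilon,
             n$add_delta_epsilon, n$add_g, seed = config$seed)
}

.cond_file <- function(condition)
  sprintf("trace_%s.csv", gsub(":", "_", condition, fixed = TRUE))

#' Pipeline stage: generate a dataset
#'
#' Writes the synthetic concentration series, the kinetic traces and the
#' three species spectra into `config$outdir`, together with a
#' `manifest.json` tying the dataset to its seed and preset version.
#' Deterministic under the config seed.
#'
#' @param config A config list from [read_run_config()].
#' @return Invisibly, the manifest list.
#' @export
pipeline_generate <- function(config = read_run_config()) {
  if (!identical(config$preset, "znchl"))
    stop(.usage_error(sprintf("unknown preset '%s'; available: znchl",
                              config$preset)))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  presets <- znchl_presets()
  noise <- .cfg_noise(config)

  grid <- default_concentration_grid(config$series$n_points,
                                     config$series$c_min,
                                     config$series$c_max)
  series <- generate_concentration_series(presets$thermo,
                                          preset_coefficients(presets),
                                          grid, noise)
  files <- character()
  f <- file.path(config$outdir, "series.csv")
  write_series_csv(series, f); files <- c(files, "series.csv")

  time_h <- seq(0, config$kinetics$t_max, by = config$kinetics$dt)
  for (cond in config$kinetics$conditions) {
    tr <- generate_kinetic_trace(cond, time_h, noise, presets)
    fn <- .cond_file(cond)
    write_trace_csv(tr, file.path(config$outdir, fn))
    files <- c(files, fn)
  }
  for (sp in c("monomer", "J1", "J2")) {
    fn <- sprintf("spectrum_%s.csv", sp)
    write_spectrum_csv(synthesize_spectrum(presets[[sp]]),
                       file.path(config$outdir, fn))
    files <- c(files, fn)
  }
  manifest <- list(seed = config$seed, preset = config$preset,
                   preset_version = presets$version,
                   noise = config$noise, files = files)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Pipeline stage: fit the concentration series
#'
#' Reads `series.csv` from `config$outdir`, fits the competing-pathway
#' model, and writes `fit_report.json` (machine-readable), `fit_report.txt`
#' (human-readable) and `landscape.csv` (Gibbs energies via
#' [energy_landscape()]).
#'
#' @inheritParams pipeline_generate
#' @return Invisibly, the [fit_concentration_series()] result.
#' @export
pipeline_fit <- function(config = read_run_config()) {
  path <- file.path(config$outdir, "series.csv")
  if (!file.exists(path))
    stop(.data_error(sprintf("input series not found: %s", path)))
  series <- read_series_csv(path)
  fit <- tryCatch(
    fit_concentration_series(series,
                             options = fit_options(
                               n_starts = config$fit$n_starts,
                               seed = config$seed),
                             T_K = config$fit$T_K),
    error = function(e) stop(.data_error(conditionMessage(e))))
  if (!fit$converged)
    stop(.nonconvergence_error("concentration-series fit did not converge"))

  land <- energy_landscape(fit$params)
  write_landscape_csv(land, file.path(config$outdir, "landscape.csv"))

  report <- list(
    constants = list(K_J1_per_M = fit$params$K_J1,
                     K_N_per_M = fit$params$K_N,
                     K_J2_per_M = fit$params$K_J2),
    T_K = fit$params$T_K,
    sigma = cooperativity(fit$params),
    dG_kJ_per_mol = stats::setNames(as.list(land$dG_kJ_per_mol),
                                    land$process),
    rss = as.list(fit$rss),
    converged = fit$converged,
    iterations = fit$iterations,
    seed = config$seed)
  jsonlite::write_json(report, file.path(config$outdir, "fit_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  txt <- c(
    "Competing-pathway equilibrium fit",
    sprintf("  K_J1 (off-pathway dimerization) = %.4g M^-1", fit$params$K_J1),
    sprintf("  K_N  (nucleation)               = %.4g M^-1", fit$params$K_N),
    sprintf("  K_J2 (elongation)               = %.4g M^-1", fit$params$K_J2),
    sprintf("  sigma = K_N/K_J2                = %.3g", cooperativity(fit$params)),
    sprintf("  dG: %s", paste(sprintf("%s %.2f kJ/mol", land$process,
                                      land$dG_kJ_per_mol), collapse = "; ")),
    sprintf("  RSS epsilon %.4g, delta-epsilon %.4g", fit$rss[1], fit$rss[2]),
    sprintf("  converged: %s after %d iterations (seed %d)",
            fit$converged, fit$iterations, config$seed))
  writeLines(txt, file.path(config$outdir, "fit_report.txt"))
  invisible(fit)
}

#' Pipeline stage: kinetic rate table
#'
#' Reads every `trace_*.csv` in `config$outdir`, estimates the initial
#' transformation rates and writes `rates.csv` ordered by water content.
#' An empty input directory yields an empty table.
#'
#' @inheritParams pipeline_generate
#' @return Invisibly, the rate table.
#' @export
pipeline_kinetics <- function(config = read_run_config()) {
  paths <- list.files(config$outdir, pattern = "^trace_.*\\.csv$",
                      full.names = TRUE)
  traces <- lapply(paths, function(p)
    tryCatch(read_trace_csv(p),
             error = function(e)
               stop(.data_error(sprintf("%s: %s", p, conditionMessage(e))))))
  rates <- tryCatch(rate_table(traces),
                    error = function(e) stop(.data_error(conditionMessage(e))))
  write_rate_table_csv(rates, file.path(config$outdir, "rates.csv"))
  invisible(rates)
}

#' Pipeline stage: landscape from a finished fit
#'
#' Re-emits `landscape.csv` from the constants in `fit_report.json`
#' (useful after editing the report temperature or to regenerate a deleted
#' export).
#'
#' @inheritParams pipeline_generate
#' @return Invisibly, the [energy_landscape()].
#' @export
pipeline_landscape <- function(config = read_run_config()) {
  path <- file.path(config$outdir, "fit_report.json")
  if (!file.exists(path))
    stop(.data_error(sprintf("fit report not found: %s (run fit first)", path)))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- thermo_params(rep$constants$K_J1_per_M, rep$constants$K_N_per_M,
                          rep$constants$K_J2_per_M, rep$T_K)
  land <- energy_landscape(params)
  write_landscape_csv(land, file.path(config$outdir, "landscape.csv"))
  invisible(land)
}

#' Pipeline stage: combined report
#'
#' Collects the fit report and rate table into one human-readable
#' `report.txt`.
#'
#' @inheritParams pipeline_generate
#' @return Invisibly, the report lines.
#' @export
pipeline_report <- function(config = read_run_config()) {
  lines <- c("jaggpath run report", sprintf("seed: %d", config$seed), "")
  fr <- file.path(config$outdir, "fit_report.txt")
  if (file.exists(fr)) lines <- c(lines, readLines(fr), "")
  rf <- file.path(config$outdir, "rates.csv")
  if (file.exists(rf)) {
    rates <- utils::read.csv(rf)
    lines <- c(lines, "Initial transformation rates d(g)/dt:",
               sprintf("  %s (%g%% water): %.4g h^-1", rates$condition,
                       rates$water_pct, rates$rate_per_h))
  }
  writeLines(lines, file.path(config$outdir, "report.txt"))
  invisible(lines)
}

#' Command-line dispatcher
#'
#' Thin entry point used by the installed `inst/cli/jaggpath.R` script.
#' Subcommands: `generate`, `fit`, `kinetics`, `landscape`, `report`.
#' Flags: `--config <yaml>`, `--seed <int>`, `--out <dir>`,
#' `--preset <name>` (flags override config). Exit codes: 0 success,
#' 2 usage error, 3 data error, 4 non-convergence.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (invisibly).
#' @export
jaggpath_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (length(args) < 1L)
      stop(.usage_error(
        "usage: jaggpath.R <generate|fit|kinetics|landscape|report> [--config f] [--seed n] [--out dir] [--preset p]"))
    cmd <- args[1]
    rest <- args[-1]
    flag <- function(name) {
      i <- which(rest == paste0("--", name))
      if (length(i) != 1L) return(NULL)
      if (i == length(rest)) stop(.usage_error(sprintf("--%s needs a value", name)))
      rest[i + 1L]
    }
    cfg <- read_run_config(flag("config"))
    if (!is.null(flag("seed"))) cfg$seed <- as.integer(flag("seed"))
    if (!is.null(flag("out"))) cfg$outdir <- flag("out")
    if (!is.null(flag("preset"))) cfg$preset <- flag("preset")
    message(sprintf("jaggpath %s: seed=%d outdir=%s preset=%s (package %s)",
                    cmd, cfg$seed, cfg$outdir, cfg$preset,
                    as.character(utils::packageVersion("jaggpath"))))
    switch(cmd,
           generate = pipeline_generate(cfg),
           fit = pipeline_fit(cfg),
           kinetics = pipeline_kinetics(cfg),
           landscape = pipeline_landscape(cfg),
           report = pipeline_report(cfg),
           stop(.usage_error(sprintf("unknown subcommand '%s'", cmd))))
    0L
  }
  status <- tryCatch(
    run(),
    jaggpath_usage_error = function(e) { message("usage error: ", conditionMessage(e)); 2L },
    jaggpath_data_error = function(e) { message("data error: ", conditionMessage(e)); 3L },
    jaggpath_nonconvergence_error = function(e) { message("non-convergence: ", conditionMessage(e)); 4L },
    error = function(e) { message("data error: ", conditionMessage(e)); 3L })
  invisible(status)
}
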