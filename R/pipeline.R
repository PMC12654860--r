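#' Pipeline configuration
#'
#' Collects every tunable parameter of the virtual-experiment pipeline
#' with units and defaults. Unknown fields are rejected; all schema
#' violations are reported together, not just the first.
#'
#' @param seed Integer master seed for all randomness.
#' @param pixel_size Camera pixel pitch (um/px).
#' @param high_strain_fraction Fraction of the achieved strain kept in
#'   the modulus fit window (see [fit_elastic_modulus()]).
#' @param checkpoint_low,checkpoint_high Strain checkpoints for the
#'   low-/high-compression rheology regimes.
#' @param bin_width Stiffness histogram bin width (kPa).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param speed Plate speed for population runs (um/s).
#' @param max_strain Target strain for population runs.
#' @param sample_rate Force/video sampling rate (Hz).
#' @param force_noise_sd Force noise (nN).
#' @param use_images If `TRUE`, population pipelines render micrographs
#'   and re-measure geometry from them instead of using the recorded
#'   geometry tables (slower; exercises the imaging path).
#' @return A validated named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, pixel_size = 0.1,
                            high_strain_fraction = 0.3,
                            checkpoint_low = 0.15, checkpoint_high = 0.45,
                            bin_width = 1, gravity = STANDARD_GRAVITY,
                            speed = 7.5, max_strain = 0.5,
                            sample_rate = 100, force_noise_sd = 2,
                            use_images = FALSE) {
  validate_config(list(
    seed = seed, pixel_size = pixel_size,
    high_strain_fraction = high_strain_fraction,
    checkpoint_low = checkpoint_low, checkpoint_high = checkpoint_high,
    bin_width = bin_width, gravity = gravity, speed = speed,
    max_strain = max_strain, sample_rate = sample_rate,
    force_noise_sd = force_noise_sd, use_images = use_images))
}

#' Validate and normalize a configuration
#'
#' Fills defaults for missing fields, rejects unknown fields, checks
#' every numeric constraint, and attaches a human-readable log header
#' (fields with units, plus a configuration hash) as attribute
#' `"log_header"`. All violations are collected and reported in one
#' error message.
#'
#' @param config A named list of configuration fields (possibly partial,
#'   e.g. parsed from JSON).
#' @return The normalized `pipeline_config`.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(seed = 1, pixel_size = 0.1, high_strain_fraction = 0.3,
                   checkpoint_low = 0.15, checkpoint_high = 0.45,
                   bin_width = 1, gravity = STANDARD_GRAVITY, speed = 7.5,
                   max_strain = 0.5, sample_rate = 100, force_noise_sd = 2,
                   use_images = FALSE)
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, sprintf("unknown field(s): %s",
                                paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])

  chk <- function(field, ok, msg) {
    if (!isTRUE(ok)) errors <<- c(errors, sprintf("`%s` %s", field, msg))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk("seed", num1(cfg$seed) && cfg$seed == round(cfg$seed),
      "must be a single integer")
  chk("pixel_size", num1(cfg$pixel_size) && cfg$pixel_size > 0,
      "must be > 0 (um/px)")
  chk("high_strain_fraction", num1(cfg$high_strain_fraction) &&
        cfg$high_strain_fraction > 0 && cfg$high_strain_fraction <= 1,
      "must lie in (0, 1]")
  chk("checkpoint_low", num1(cfg$checkpoint_low) && cfg$checkpoint_low > 0 &&
        cfg$checkpoint_low < 1, "must lie in (0, 1)")
  chk("checkpoint_high", num1(cfg$checkpoint_high) &&
        cfg$checkpoint_high > 0 && cfg$checkpoint_high < 1,
      "must lie in (0, 1)")
  chk("bin_width", num1(cfg$bin_width) && cfg$bin_width > 0,
      "must be > 0 (kPa)")
  chk("gravity", num1(cfg$gravity) && cfg$gravity > 0, "must be > 0 (m/s^2)")
  chk("speed", num1(cfg$speed) && cfg$speed > 0, "must be > 0 (um/s)")
  chk("max_strain", num1(cfg$max_strain) && cfg$max_strain > 0 &&
        cfg$max_strain < 1, "must lie in (0, 1)")
  chk("sample_rate", num1(cfg$sample_rate) && cfg$sample_rate > 0,
      "must be > 0 (Hz)")
  chk("force_noise_sd", num1(cfg$force_noise_sd) && cfg$force_noise_sd >= 0,
      "must be >= 0 (nN)")
  chk("use_images", is.logical(cfg$use_images) && length(cfg$use_images) == 1,
      "must be TRUE or FALSE")
  if (length(errors))
    stopf("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))

  units <- c(seed = "", pixel_size = "um/px", high_strain_fraction = "",
             checkpoint_low = "strain", checkpoint_high = "strain",
             bin_width = "kPa", gravity = "m/s^2", speed = "um/s",
             max_strain = "strain", sample_rate = "Hz",
             force_noise_sd = "nN", use_images = "")
  hash <- config_hash(cfg)
  header <- c(sprintf("micropress %s config %s",
                      as.character(utils::packageVersion("micropress")), hash),
              vapply(names(defaults), function(f) {
                sprintf("%s = %s %s", f, format(cfg[[f]]), units[[f]])
              }, character(1)))
  structure(cfg, log_header = header, class = "pipeline_config")
}

# Stable fingerprint of a configuration (hash of its canonical JSON).
config_hash <- function(cfg) {
  fnv1a_hash(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              digits = NA))
}

#' @export
print.pipeline_config <- function(x, ...) {
  writeLines(attr(x, "log_header"))
  invisible(x)
}

#' Measure one virtual cell's elastic modulus end to end
#'
#' Composes the full measurement chain for a single cell: simulate the
#' compression, optionally render micrographs and re-measure the
#' geometry from them, build the stress-strain curve, and regress the
#' modulus from the high-strain window.
#'
#' @param cell A [virtual_cell_params()].
#' @param config A [pipeline_config()].
#' @param seed Integer seed for this cell's noise.
#' @return A [fit_elastic_modulus()] result.
#' @export
measure_cell_modulus <- function(cell, config = pipeline_config(), seed = 1) {
  run <- compression_run_spec(speed = config$speed,
                              max_strain = config$max_strain,
                              sample_rate = config$sample_rate,
                              force_noise_sd = config$force_noise_sd)
  rec <- simulate_compression(cell, run, seed = seed)
  if (isTRUE(config$use_images)) {
    every <- max(1L, floor(nrow(rec$data) / 20))   # video-like frame rate
    idx <- seq(1, nrow(rec$data), by = every)
    frames <- render_stack(rec, pixel_size = config$pixel_size,
                           every = every)
    geom <- measure_stack(frames)
    rec <- compression_record(rec$data$time_s[idx], rec$data$force_nN[idx],
                              geom$Dt_um, geom$Lt_um, speed = rec$speed)
  }
  fit_elastic_modulus(build_curve(rec), config$high_strain_fraction)
}

# Full pipeline over a sampled population -> cell_population of fitted E.
measure_population <- function(preset, n, config, seed) {
  cells <- sample_population(preset, n, seed = seed)
  E <- vapply(seq_along(cells), function(i) {
    measure_cell_modulus(cells[[i]], config, seed = seed + i)$E_kPa
  }, numeric(1))
  structure(cell_population(E, attr(cells, "condition")),
            true_moduli = attr(cells, "moduli"))
}

# Scenario registry: each entry simulates, analyzes, and returns a report.
scenario_names <- function() {
  c("cell_panel", "cd_dose", "tsa_dose", "trypsinization", "progerin",
    "rheology_sweep", "needle_vs_plate")
}

#' Run a named virtual experiment
#'
#' Simulates one of the built-in experiment scenarios with the full
#' measurement pipeline and returns (and optionally writes) its report.
#' Scenarios:
#' \describe{
#'   \item{`cell_panel`}{stiffness of five cell lines at their reported
#'     sample sizes; per-condition summaries.}
#'   \item{`cd_dose`}{Cytochalasin D dose series with dose-response
#'     monotonicity check and pairwise t-tests against control.}
#'   \item{`tsa_dose`}{Trichostatin A dose series, same analyses.}
#'   \item{`trypsinization`}{trypsinized vs non-trypsinized comparison
#'     with a t-test.}
#'   \item{`progerin`}{wild-type vs lamin A vs progerin overexpression;
#'     histogram densities and mode detection per condition.}
#'   \item{`rheology_sweep`}{speed sweep (2.5-15 um/s) of a
#'     viscoelastic two-compartment cell; power-law fits per
#'     compression regime and their comparison.}
#'   \item{`needle_vs_plate`}{max-force distributions for needle vs
#'     plate end-effectors on one population.}
#' }
#' Identical seeds and configs give identical outputs.
#'
#' @param scenario Scenario name, see above.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, population CSVs,
#'   summary CSVs, and a JSON report are written, each stamped with the
#'   configuration hash.
#' @param n_progerin Cells per condition in the `progerin` scenario.
#' @return The report, a named list (invisibly when writing).
#' @export
run_virtual_experiment <- function(scenario, config = pipeline_config(),
                                   out_dir = NULL, n_progerin = 100) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (!scenario %in% scenario_names())
    stopf("unknown scenario '%s'; known: %s", scenario,
          paste(scenario_names(), collapse = ", "))
  seed <- config$seed
  report <- switch(scenario,
    cell_panel = scenario_populations(
      c("HEK293A", "C2C12", "HeLa", "10T1/2", "UE7T-13"), config, seed),
    cd_dose = scenario_dose(c("CD_untreated", "CD_1uM", "CD_2uM"),
                            config, seed),
    tsa_dose = scenario_dose(c("TSA_control", "TSA_250nM", "TSA_500nM"),
                             config, seed),
    trypsinization = scenario_pair("trypsinized", "non_trypsinized",
                                   config, seed),
    progerin = scenario_progerin(config, seed, n_progerin),
    rheology_sweep = scenario_rheology(config, seed),
    needle_vs_plate = scenario_end_effector(config, seed)
  )
  report$scenario <- scenario
  report$config_hash <- config_hash(config)
  if (!is.null(out_dir)) {
    write_experiment_report(report, out_dir, config)
    return(invisible(report))
  }
  report
}

scenario_populations <- function(conditions, config, seed) {
  pops <- lapply(seq_along(conditions), function(i) {
    p <- preset_registry(conditions[i])
    n <- if (is.na(p$n_reported)) 30L else p$n_reported
    measure_population(p, n, config, seed + 1000L * i)
  })
  names(pops) <- conditions
  list(populations = pops,
       summaries = do.call(rbind, lapply(pops, summarize_population)))
}

scenario_dose <- function(conditions, config, seed) {
  rep0 <- scenario_populations(conditions, config, seed)
  rep0$dose_response <- dose_response_check(rep0$summaries)
  rep0$t_tests <- lapply(conditions[-1], function(cn) {
    students_t_test(rep0$populations[[conditions[1]]],
                    rep0$populations[[cn]])
  })
  names(rep0$t_tests) <- paste(conditions[1], "vs", conditions[-1])
  rep0
}

scenario_pair <- function(a, b, config, seed) {
  rep0 <- scenario_populations(c(a, b), config, seed)
  rep0$t_test <- students_t_test(rep0$populations[[a]],
                                 rep0$populations[[b]])
  rep0
}

scenario_progerin <- function(config, seed, n) {
  conditions <- c("WT", "LaminA_OX", "Progerin_OX")
  pops <- lapply(seq_along(conditions), function(i) {
    measure_population(preset_registry(conditions[i]), n, config,
                       seed + 1000L * i)
  })
  names(pops) <- conditions
  list(populations = pops,
       summaries = do.call(rbind, lapply(pops, summarize_population)),
       histograms = lapply(pops, histogram_density,
                           bin_width = config$bin_width),
       modes = lapply(pops, detect_modes))
}

scenario_rheology <- function(config, seed,
                              speeds = c(2.5, 5, 10, 15),
                              cell = virtual_cell_params()) {
  samples <- lapply(c(low = config$checkpoint_low,
                      high = config$checkpoint_high), function(cp) {
    do.call(rbind, lapply(seq_along(speeds), function(i) {
      run <- compression_run_spec(speed = speeds[i],
                                  max_strain = max(0.6, cp + 0.05),
                                  sample_rate = config$sample_rate,
                                  force_noise_sd = config$force_noise_sd)
      rec <- simulate_compression(cell, run, seed = seed + i)
      apparent_modulus_at_checkpoint(
        build_curve(rec), rec, cp,
        nucleus_contact_strain = 1 - cell$nucleus_fraction)
    }))
  })
  fits <- lapply(samples, fit_power_law)
  list(samples = samples, fit_low = fits$low, fit_high = fits$high,
       regimes = compare_regimes(fits$low, fits$high))
}

scenario_end_effector <- function(config, seed, n = 50) {
  moduli <- sample_moduli("HEK293A", n, seed = seed)
  run <- compression_run_spec(speed = config$speed,
                              max_strain = config$max_strain,
                              sample_rate = config$sample_rate,
                              force_noise_sd = config$force_noise_sd)
  panel <- simulate_end_effector_panel(moduli, run, seed = seed)
  v <- tapply(panel$max_force_nN, panel$scenario, stats::var)
  list(panel = panel,
       var_plate = unname(v[["plate"]]), var_needle = unname(v[["needle"]]),
       needle_broader = v[["needle"]] > v[["plate"]])
}

# Write a scenario report: per-condition moduli CSV, summary CSV, and a
# JSON report, each stamped with the configuration hash.
write_experiment_report <- function(report, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- sprintf("config %s", report$config_hash)
  if (!is.null(report$populations))
    write_population_csv(report$populations,
                         file.path(out_dir, "moduli.csv"), header = hash)
  if (!is.null(report$summaries)) {
    con <- file(file.path(out_dir, "summaries.csv"), "w")
    writeLines(paste0("# ", hash), con)
    utils::write.csv(report$summaries, con, row.names = FALSE)
    close(con)
  }
  json <- report
  json$populations <- lapply(json$populations, `[[`, "moduli")
  json$panel <- NULL
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
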