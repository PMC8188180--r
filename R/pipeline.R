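#' Forward simulation from a scenario configuration
#'
#' Runs the full forward pipeline -- build the grid, solve the steady
#' diffusion-reaction equation at the configured `Q_m`, post-process -- and
#' optionally writes the contour-ready field export and a summary table to an
#' output directory. The fully resolved configuration (all defaults
#' materialised) is logged so a run is reproducible from its log alone.
#'
#' @param config A validated configuration list or the path of a YAML file
#'   (see [read_scenario_config()]).
#' @param out_dir Output directory; `NULL` (default `run$output_dir`)
#'   disables file output.
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with the solved `field`, its [oxygen_summary()]
#'   `summary`, and the written `paths` (if any).
#' @export
run_simulate <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- load_config(config)
  obj <- cfg$objects
  log_msg(quiet, "resolved config: %s", deparse1(summary_config(obj)))
  grid <- build_domain(obj$geometry, resolution = obj$solver$resolution)
  field <- solve_steady(grid, obj$params, obj$density, obj$solver$Q_m,
                        tol_change = obj$solver$tol_change,
                        tol_flux = obj$solver$tol_flux,
                        max_iter = obj$solver$max_iter)
  log_msg(quiet, "solved in %d iterations, flux imbalance %.2e",
          field$iterations, field$flux_imbalance)
  summ <- oxygen_summary(field)
  paths <- NULL
  out_dir <- out_dir %||% obj$run$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(field = file.path(out_dir, "field.tsv"),
               summary = file.path(out_dir, "summary.tsv"))
    export_contour(field, paths[["field"]])
    write_summary_table(summ, paths[["summary"]])
  }
  invisible(list(field = field, summary = summ, paths = paths))
}

#' Batch inversion from a configuration and a readings table
#'
#' Loads sensor readings, fits one `Q_m` per reading against the configured
#' scenario with [fit_qm_batch()], and optionally writes the estimate table.
#'
#' @inheritParams run_simulate
#' @param readings A readings data frame or the path of a readings file
#'   (see [read_sensor_readings()]).
#' @param epsilon Depletion threshold (% O2) for readings at 0.
#' @return Invisibly, the estimates data frame (with the `"summary"`
#'   attribute of [fit_qm_batch()]).
#' @export
run_fit <- function(config, readings, out_dir = NULL, epsilon = 0.05,
                    quiet = FALSE) {
  cfg <- load_config(config)
  obj <- cfg$objects
  if (is.character(readings)) readings <- read_sensor_readings(readings)
  log_msg(quiet, "fitting %d readings (resolved config: %s)",
          nrow(readings), deparse1(summary_config(obj)))
  grid <- build_domain(obj$geometry, resolution = obj$solver$resolution)
  est <- fit_qm_batch(readings, grid, obj$params, obj$density,
                      epsilon = epsilon)
  out_dir <- out_dir %||% obj$run$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(est, file.path(out_dir, "qm_estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(est)
}

#' Full study-arm report for a preset scenario
#'
#' Reproduces the analysis shape of one study arm: a day-0 and a day-24
#' forward run at the arm's consumption rates and densities, the fitted `Q_m`
#' recovered from a noiseless synthetic central reading at each day, and the
#' region means and volumetric frequency tables of both fields.
#'
#' @param preset Arm name without the day suffix (e.g. `"cc_20pct_20M"`), or
#'   a full preset name (e.g. `"cc_20pct_20M_day0"`) for a single day.
#' @param resolution Grid spacing (mm).
#' @param seed Seed recorded in the report (forward runs are deterministic).
#' @param quiet Suppress log messages.
#' @return A list with one element per day: the scenario `spec`, the solved
#'   `summary`, and the `fitted` [fit_qm()] estimate.
#' @export
run_scenario <- function(preset, resolution = 0.1, seed = 1L, quiet = FALSE) {
  presets <- preset_scenarios(seed = seed)
  nms <- if (preset %in% names(presets)) preset
         else grep(paste0("^", preset, "_day"), names(presets), value = TRUE)
  if (length(nms) == 0L)
    stop("unknown preset '", preset, "'; available: ",
         paste(unique(sub("_day\\d+$", "", names(presets))), collapse = ", "))
  grid <- build_domain(construct_geometry(), resolution = resolution)
  report <- list()
  for (nm in nms) {
    spec <- presets[[nm]]
    params <- scenario_params(spec)
    density <- scenario_density(spec)
    log_msg(quiet, "%s: forward solve at Q_m = %.4g", nm, spec$true_qm)
    field <- solve_steady(grid, params, density, spec$true_qm)
    truth <- central_o2(field)
    fitted <- if (truth > 0.05)
      fit_qm(truth, grid, params, density)
    else
      min_qm_for_depletion(grid, params, density)
    report[[nm]] <- list(spec = spec, summary = oxygen_summary(field),
                         fitted = fitted)
  }
  report
}

#' Generate a synthetic fixture bundle for a preset
#'
#' @inheritParams run_scenario
#' @param path Directory to write the bundle into.
#' @return Invisibly, the file paths written (see [write_fixture_bundle()]).
#' @export
run_synth <- function(preset, path, seed = 1L, resolution = 0.25) {
  presets <- preset_scenarios(seed = seed)
  if (!preset %in% names(presets))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "))
  write_fixture_bundle(presets[[preset]], path, resolution = resolution)
}

load_config <- function(config) {
  if (is.character(config)) {
    dir <- dirname(config)
    config <- read_scenario_config(config)
  } else {
    dir <- "."
    validate_scenario_config(config)
  }
  list(config = config, objects = config_to_objects(config, config_dir = dir))
}

summary_config <- function(obj) {
  c(C_surface_uM = obj$params$C_surface, K_m_uM = obj$params$K_m,
    rho_core = obj$density$construct_core,
    rho_annulus = obj$density$construct_annulus,
    resolution_mm = obj$solver$resolution, Q_m = obj$solver$Q_m)
}

log_msg <- function(quiet, fmt, ...) {
  if (!quiet)
    message(format(Sys.time(), "%H:%M:%S "), sprintf(fmt, ...))
}

write_summary_table <- function(summ, path) {
  df <- data.frame(
    metric = c("central_o2_percent",
               "core_mean_o2_percent", "annulus_mean_o2_percent",
               "core_fraction_below_threshold",
               "annulus_fraction_below_threshold"),
    value = c(summ$central_o2,
              summ$region_means[["construct_core"]],
              summ$region_means[["construct_annulus"]],
              summ$fraction_below[["construct_core"]],
              summ$fraction_below[["construct_annulus"]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
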