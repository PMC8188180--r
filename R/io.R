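#' Read and write sensor reading tables
#'
#' Tab-separated tables with header `sample_id`, `day`, `condition`,
#' `o2c_percent` (an optional `replicate` column is preserved). Oxygen levels
#' must be non-negative.
#'
#' @param path File path.
#' @param readings Data frame of readings.
#' @return `read_sensor_readings` returns the validated data frame;
#'   `write_sensor_readings` returns `path` invisibly.
#' @export
read_sensor_readings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "day", "condition", "o2c_percent")
  if (!all(req %in% names(df)))
    stop("readings file must have columns ", paste(req, collapse = ", "))
  if (nrow(df) == 0L) stop("readings file '", path, "' contains no rows")
  if (any(df$o2c_percent < 0)) stop("o2c_percent must be non-negative")
  df
}

#' @rdname read_sensor_readings
#' @export
write_sensor_readings <- function(readings, path) {
  utils::write.table(readings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write biochemical assay tables
#'
#' Tab-separated tables with header `sample_id`, `day`, `region`,
#' `wet_weight_mg`, `dna_ug`, `sgag_ug`, `hyp_ug`.
#'
#' @param path File path.
#' @param assays Data frame of assay samples.
#' @return `read_assay_samples` returns the validated data frame;
#'   `write_assay_samples` returns `path` invisibly.
#' @export
read_assay_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "day", "region", "wet_weight_mg", "dna_ug",
           "sgag_ug", "hyp_ug")
  if (!all(req %in% names(df)))
    stop("assay file must have columns ", paste(req, collapse = ", "))
  if (!all(df$region %in% c("core", "annulus", "whole")))
    stop("assay region must be one of 'core', 'annulus', 'whole'")
  df
}

#' @rdname read_assay_samples
#' @export
write_assay_samples <- function(assays, path) {
  utils::write.table(assays, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

config_schema <- list(
  geometry = c("construct_radius_mm", "construct_height_mm", "core_radius_mm",
               "dish_radius_mm", "bed_depth_mm", "recess_depth_mm",
               "media_depth_mm"),
  parameters = c("d_media_mm2_s", "d_ag_mm2_s", "phi_f", "k_m_uM",
                 "c_surface_uM", "uM_per_percent", "rho0_cells_per_mL"),
  density = c("day", "rho_core_cells_per_mL", "rho_annulus_cells_per_mL",
              "assay_table"),
  solver = c("resolution_mm", "tol_change", "tol_flux", "max_iter",
             "q_m_amol_cell_s"),
  run = c("seed", "output_dir"))

#' Read, validate and write scenario configuration files
#'
#' A scenario configuration is a YAML file with up to five blocks --
#' `geometry`, `parameters`, `density`, `solver`, `run` -- whose keys mirror
#' the constructors' arguments in explicit units (mm, uM, cells/mL). Unknown
#' blocks or keys are rejected so that a mistyped unit suffix cannot silently
#' fall back to a default; omitted keys take the documented defaults. A
#' `density$assay_table` path, when given, must exist at load time.
#'
#' @param path YAML file path.
#' @param config Named list with the structure above.
#' @return `read_scenario_config` returns the validated list;
#'   `write_scenario_config` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file '", path, "' does not exist")
  config <- yaml::read_yaml(path)
  validate_scenario_config(config, dir = dirname(path))
  config
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  validate_scenario_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_scenario_config <- function(config, dir = ".") {
  if (!is.list(config)) stop("config must be a named list")
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (block in names(config)) {
    bad <- setdiff(names(config[[block]]), config_schema[[block]])
    if (length(bad))
      stop("unknown key(s) in config block '", block, "': ",
           paste(bad, collapse = ", "))
  }
  at <- config$density$assay_table
  if (!is.null(at)) {
    p <- if (file.exists(at)) at else file.path(dir, at)
    if (!file.exists(p))
      stop("density$assay_table file '", at, "' does not exist")
  }
  invisible(config)
}

# Materialise model objects from a validated config (all defaults filled in).
config_to_objects <- function(config, config_dir = ".") {
  gb <- config$geometry
  geometry <- construct_geometry(
    construct_radius = gb$construct_radius_mm %||% 2.5,
    construct_height = gb$construct_height_mm %||% 3.0,
    core_radius = gb$core_radius_mm %||% 1.5,
    dish_radius = gb$dish_radius_mm %||% 30.0,
    bed_depth = gb$bed_depth_mm %||% 3.0,
    recess_depth = gb$recess_depth_mm %||% 1.5,
    media_depth = gb$media_depth_mm %||% 1.0)
  pb <- config$parameters
  params <- model_parameters(
    D_media = pb$d_media_mm2_s %||% 3.0e-3,
    phi_f = pb$phi_f %||% 0.98,
    D_ag = pb$d_ag_mm2_s,
    K_m = pb$k_m_uM %||% 63,
    C_surface = pb$c_surface_uM %||% 185,
    uM_per_percent = pb$uM_per_percent %||% 9.25,
    rho0 = pb$rho0_cells_per_mL %||% 20e6)
  db <- config$density
  day <- db$day %||% 0
  if (!is.null(db$assay_table)) {
    at <- if (file.exists(db$assay_table)) db$assay_table
          else file.path(config_dir, db$assay_table)
    density <- build_density_map(read_assay_samples(at), params$rho0,
                                 day = day, geometry = geometry)
  } else if (!is.null(db$rho_core_cells_per_mL)) {
    density <- cell_density_map(db$rho_core_cells_per_mL,
                                db$rho_annulus_cells_per_mL %||%
                                  db$rho_core_cells_per_mL, day = day)
  } else {
    density <- cell_density_map(params$rho0, params$rho0, day = day)
  }
  sb <- config$solver
  solver <- list(resolution = sb$resolution_mm %||% 0.1,
                 tol_change = sb$tol_change %||% 1e-8,
                 tol_flux = sb$tol_flux %||% 1e-6,
                 max_iter = sb$max_iter %||% 500L,
                 Q_m = sb$q_m_amol_cell_s %||% 0)
  run <- list(seed = config$run$seed %||% 1L,
              output_dir = config$run$output_dir)
  list(geometry = geometry, params = params, density = density,
       solver = solver, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
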