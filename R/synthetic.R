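# Run code with a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic study arm
#'
#' Describes one study arm at one time point for the synthetic-data
#' generator: cell source, external oxygen condition, seeding density, the
#' generator's true consumption rate, the per-region DNA growth ratios, and
#' the noise model (additive Gaussian sensor noise in % O2 clipped at zero;
#' multiplicative lognormal assay noise).
#'
#' @param name Scenario name.
#' @param cell_source One of `"BMSC"`, `"FPSC"`, `"CC"`.
#' @param day Culture day (0 or 24).
#' @param external_o2_percent Nominal incubator oxygen (%).
#' @param C_surface Oxygen concentration at the medium surface (uM).
#' @param rho0 Seeding density (cells/mL).
#' @param true_qm Generator's true consumption rate (amol/cell/s).
#' @param dna_ratio_core,dna_ratio_annulus Day-24/day-0 DNA ratio per region
#'   (1 at day 0).
#' @param noise_sd Sensor noise SD (% O2).
#' @param assay_cv Assay coefficient of variation (fraction).
#' @param n_replicates Replicates per condition.
#' @param seed Random seed recorded in all outputs.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(name, cell_source, day, external_o2_percent,
                          C_surface, rho0, true_qm,
                          dna_ratio_core = 1, dna_ratio_annulus = 1,
                          noise_sd = 0.3, assay_cv = 0.10,
                          n_replicates = 3L, seed = 1L) {
  if (!cell_source %in% c("BMSC", "FPSC", "CC"))
    stop("cell_source must be BMSC, FPSC or CC")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (noise_sd < 0 || assay_cv < 0) stop("noise levels must be non-negative")
  if (true_qm < 0 || rho0 <= 0 || C_surface <= 0)
    stop("true_qm must be non-negative; rho0 and C_surface positive")
  structure(list(name = name, cell_source = cell_source, day = day,
                 external_o2_percent = external_o2_percent,
                 C_surface = C_surface, rho0 = rho0, true_qm = true_qm,
                 dna_ratio_core = dna_ratio_core,
                 dna_ratio_annulus = dna_ratio_annulus,
                 noise_sd = noise_sd, assay_cv = assay_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(paste0("Scenario %s: %s, day %d, %g%% O2 (%g uM), ",
                     "%.3g cells/mL, true Q_m %.4g amol/cell/s\n"),
              x$name, x$cell_source, x$day, x$external_o2_percent,
              x$C_surface, x$rho0, x$true_qm))
  invisible(x)
}

#' Preset synthetic scenarios for the supported study arms
#'
#' One preset per study arm and time point: the three cell sources (BMSC,
#' FPSC, CC) at 20% oxygen and 20e6 cells/mL, the BMSC low-oxygen arm (5%),
#' and the BMSC high-density arm (40e6 cells/mL), each at day 0 and day 24.
#' The generator truths are the reported consumption rates per arm (BMSC
#' 43.2/13.1, FPSC 28.1/19.1, CC 18.1/14.9, BMSC at 5% O2 8.7 by day 24) and
#' the reported DNA changes (stem cells ~40% increase, chondrocytes ~20%
#' decrease). Day-0 rates for the low-oxygen and high-density arms reuse the
#' BMSC day-0 value, the same cell population.
#'
#' @param seed Seed recorded in every preset.
#' @return Named list of [scenario_spec()] objects.
#' @examples
#' names(preset_scenarios())
#' @export
preset_scenarios <- function(seed = 1L) {
  arms <- list(
    list(base = "bmsc_20pct_20M", src = "BMSC", o2 = 20, C = 185, rho = 20e6,
         qm = c(43.2, 13.1), ratio = 1.4),
    list(base = "fpsc_20pct_20M", src = "FPSC", o2 = 20, C = 185, rho = 20e6,
         qm = c(28.1, 19.1), ratio = 1.4),
    list(base = "cc_20pct_20M", src = "CC", o2 = 20, C = 185, rho = 20e6,
         qm = c(18.1, 14.9), ratio = 0.8),
    list(base = "bmsc_5pct_20M", src = "BMSC", o2 = 5, C = 50, rho = 20e6,
         qm = c(43.2, 8.7), ratio = 1.4),
    list(base = "bmsc_20pct_40M", src = "BMSC", o2 = 20, C = 185, rho = 40e6,
         qm = c(43.2, 13.1), ratio = 1.4))
  out <- list()
  for (a in arms) {
    for (d in c(0L, 24L)) {
      nm <- paste0(a$base, "_day", d)
      ratio <- if (d == 0L) 1 else a$ratio
      out[[nm]] <- scenario_spec(nm, a$src, d, a$o2, a$C, a$rho,
                                 true_qm = if (d == 0L) a$qm[1] else a$qm[2],
                                 dna_ratio_core = ratio,
                                 dna_ratio_annulus = ratio,
                                 seed = seed)
    }
  }
  out
}

#' Model objects implied by a scenario
#'
#' `scenario_density` builds the scenario's [cell_density_map()] (uniform
#' seeding at day 0; seeding density scaled by the per-region DNA ratios at
#' day 24). `scenario_params` builds [model_parameters()] with the scenario's
#' surface concentration and seeding density.
#'
#' @param spec A [scenario_spec()].
#' @return A `cell_density_map` or `model_parameters` object.
#' @export
scenario_density <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$day == 0)
    cell_density_map(spec$rho0, spec$rho0, day = 0)
  else
    cell_density_map(spec$rho0 * spec$dna_ratio_core,
                     spec$rho0 * spec$dna_ratio_annulus, day = spec$day)
}

#' @rdname scenario_density
#' @export
scenario_params <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  model_parameters(C_surface = spec$C_surface, rho0 = spec$rho0)
}

#' Simulate central oxygen sensor readings for a scenario
#'
#' Emulates the fiber-optic point measurement at the construct centre: the
#' forward model's central oxygen level at the scenario's true `Q_m`, plus
#' additive Gaussian noise (SD = `spec$noise_sd`, % O2) clipped at zero, once
#' per replicate. Reproducible for a fixed scenario seed.
#'
#' @param spec A [scenario_spec()].
#' @param grid An [build_domain()] grid.
#' @param params Model parameters; defaults to [scenario_params()].
#' @return Data frame `sample_id`, `day`, `condition`, `o2c_percent`,
#'   `replicate`.
#' @export
simulate_readings <- function(spec, grid, params = scenario_params(spec)) {
  stopifnot(inherits(spec, "scenario_spec"))
  field <- solve_steady(grid, params, scenario_density(spec), spec$true_qm)
  truth <- central_o2(field)
  with_seed(spec$seed, {
    noise <- stats::rnorm(spec$n_replicates, 0, spec$noise_sd)
    data.frame(
      sample_id = sprintf("%s_r%d", spec$name, seq_len(spec$n_replicates)),
      day = spec$day,
      condition = spec$name,
      o2c_percent = pmax(truth + noise, 0),
      replicate = seq_len(spec$n_replicates))
  })
}

# Matrix-response fixtures: deposition increases as regional oxygen falls
# (logistic in % O2), and collagen synthesis is additionally suppressed below
# a 2% O2 knee. These are test fixtures with configurable parameters, not
# mechanistic claims.
sgag_response_percent_ww <- function(o2_percent, base = 0.4, span = 1.6,
                                     o2_half = 8, width = 3) {
  base + span / (1 + exp((o2_percent - o2_half) / width))
}

collagen_response_percent_ww <- function(o2_percent, base = 0.05, span = 0.55,
                                         o2_half = 8, width = 3,
                                         knee = 2, knee_width = 0.5) {
  (base + span / (1 + exp((o2_percent - o2_half) / width))) /
    (1 + exp((knee - o2_percent) / knee_width))
}

#' Simulate biochemical assay samples for a scenario
#'
#' Emulates per-region wet weight, DNA, sGAG and hydroxyproline readouts.
#' DNA per region is the seeded baseline (cells in the region times an
#' assumed 7.7 pg DNA/cell) scaled by the scenario's DNA growth ratio, with
#' multiplicative lognormal noise of coefficient of variation `spec$assay_cv`.
#' Matrix masses respond to the region's mean oxygen level: sGAG deposition
#' increases as oxygen falls, and collagen is additionally suppressed below
#' 2% O2; both accrue linearly with culture day. Wet weight assumes a tissue
#' density of 1 mg/mm^3.
#'
#' @param spec A [scenario_spec()].
#' @param grid An [build_domain()] grid.
#' @param params Model parameters; defaults to [scenario_params()].
#' @param field Optional pre-computed [solve_steady()] field at the
#'   scenario's true `Q_m` (solved internally when `NULL`).
#' @param dna_per_cell_pg Assumed DNA content per cell (pg).
#' @return Data frame `sample_id`, `day`, `region`, `wet_weight_mg`,
#'   `dna_ug`, `sgag_ug`, `hyp_ug`.
#' @export
simulate_assays <- function(spec, grid, params = scenario_params(spec),
                            field = NULL, dna_per_cell_pg = 7.7) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(field))
    field <- solve_steady(grid, params, scenario_density(spec), spec$true_qm)
  geom <- grid$geometry
  vol <- c(core = pi * geom$core_radius^2 * geom$construct_height,
           annulus = pi * (geom$construct_radius^2 - geom$core_radius^2) *
             geom$construct_height)
  mean_o2 <- c(core = region_mean_o2(field, "construct_core"),
               annulus = region_mean_o2(field, "construct_annulus"))
  ratio <- c(core = spec$dna_ratio_core, annulus = spec$dna_ratio_annulus)
  if (spec$day == 0) ratio[] <- 1
  maturity <- spec$day / 24
  cv <- spec$assay_cv
  sdlog <- sqrt(log(1 + cv^2))
  lognoise <- function(n) {
    if (cv == 0) rep(1, n) else stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  with_seed(spec$seed + 1L, {
    rows <- list()
    for (rep_i in seq_len(spec$n_replicates)) {
      for (rg in c("core", "annulus")) {
        ww_mg <- vol[[rg]] * 1.0
        cells <- spec$rho0 * 1e-3 * vol[[rg]]   # cells/mm^3 * mm^3
        dna_base <- cells * dna_per_cell_pg * 1e-6  # pg -> ug
        dna <- dna_base * ratio[[rg]] * lognoise(1)
        sgag <- sgag_response_percent_ww(mean_o2[[rg]]) / 100 *
          (ww_mg * 1000) * maturity * lognoise(1)
        collagen <- collagen_response_percent_ww(mean_o2[[rg]]) / 100 *
          (ww_mg * 1000) * maturity * lognoise(1)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_r%d", spec$name, rep_i),
          day = spec$day, region = rg, wet_weight_mg = ww_mg,
          dna_ug = dna, sgag_ug = sgag,
          hyp_ug = collagen / 7.69)
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a self-contained synthetic fixture bundle
#'
#' Generates readings and assays for a scenario (plus the day-0 assay
#' baseline when the scenario is a later time point) and writes them together
#' with the matching pipeline configuration and a manifest recording the seed
#' and all generator parameters. Regeneration with the same spec is
#' byte-identical.
#'
#' @param spec A [scenario_spec()].
#' @param path Directory to create/fill.
#' @param resolution Grid spacing (mm) for the embedded forward solves.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture_bundle <- function(spec, path, resolution = 0.25) {
  stopifnot(inherits(spec, "scenario_spec"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  geom <- construct_geometry()
  grid <- build_domain(geom, resolution = resolution)
  params <- scenario_params(spec)
  readings <- simulate_readings(spec, grid, params)
  assays <- simulate_assays(spec, grid, params)
  if (spec$day != 0) {
    spec0 <- spec
    spec0$day <- 0L
    spec0$true_qm <- spec$true_qm  # same forward model only for assay baseline
    assays <- rbind(simulate_assays(spec0, grid, params), assays)
  }
  files <- c(readings = file.path(path, "readings.tsv"),
             assays = file.path(path, "assays.tsv"),
             config = file.path(path, "scenario.yaml"),
             manifest = file.path(path, "manifest.yaml"))
  write_sensor_readings(readings, files[["readings"]])
  write_assay_samples(assays, files[["assays"]])
  density <- scenario_density(spec)
  config <- list(
    geometry = list(construct_radius_mm = geom$construct_radius,
                    construct_height_mm = geom$construct_height,
                    core_radius_mm = geom$core_radius,
                    dish_radius_mm = geom$dish_radius,
                    bed_depth_mm = geom$bed_depth,
                    recess_depth_mm = geom$recess_depth,
                    media_depth_mm = geom$media_depth),
    parameters = list(d_media_mm2_s = params$D_media,
                      phi_f = params$phi_f,
                      k_m_uM = params$K_m,
                      c_surface_uM = params$C_surface,
                      uM_per_percent = params$uM_per_percent,
                      rho0_cells_per_mL = params$rho0),
    density = list(day = spec$day,
                   rho_core_cells_per_mL = density$construct_core,
                   rho_annulus_cells_per_mL = density$construct_annulus),
    solver = list(resolution_mm = resolution,
                  q_m_amol_cell_s = spec$true_qm),
    run = list(seed = spec$seed))
  write_scenario_config(config, files[["config"]])
  manifest <- unclass(spec)
  manifest$package <- "oxygel"
  yaml::write_yaml(manifest, files[["manifest"]])
  invisible(files)
}
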