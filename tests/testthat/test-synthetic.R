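test_that("presets enumerate every study arm at both time points", {
  presets <- preset_scenarios()
  expect_length(presets, 10)  # 5 arms x 2 days
  expect_equal(presets$bmsc_20pct_20M_day0$true_qm, 43.2)
  expect_equal(presets$bmsc_20pct_20M_day24$true_qm, 13.1)
  expect_equal(presets$cc_20pct_20M_day0$true_qm, 18.1)
  expect_equal(presets$cc_20pct_20M_day24$dna_ratio_core, 0.8)
  expect_equal(presets$fpsc_20pct_20M_day0$true_qm, 28.1)
  expect_equal(presets$bmsc_5pct_20M_day24$C_surface, 50)
  expect_equal(presets$bmsc_5pct_20M_day24$true_qm, 8.7)
  expect_equal(presets$bmsc_20pct_40M_day0$rho0, 40e6)
})

test_that("scenario densities follow the day and DNA ratios", {
  presets <- preset_scenarios()
  d0 <- scenario_density(presets$bmsc_20pct_20M_day0)
  expect_equal(d0$construct_core, 20e6)
  d24 <- scenario_density(presets$bmsc_20pct_20M_day24)
  expect_equal(d24$construct_core, 28e6)
  expect_equal(scenario_density(presets$cc_20pct_20M_day24)$construct_core,
               16e6)
})

test_that("noiseless readings equal the forward prediction exactly", {
  spec <- scenario_spec("test", "CC", 0, 20, 185, 20e6, true_qm = 18.1,
                        noise_sd = 0, n_replicates = 3, seed = 7)
  grid <- coarse_grid()
  readings <- simulate_readings(spec, grid)
  truth <- central_o2(solve_steady(grid, scenario_params(spec),
                                   scenario_density(spec), 18.1))
  expect_equal(readings$o2c_percent, rep(truth, 3))
})

test_that("reading simulation is deterministic under a fixed seed", {
  spec <- scenario_spec("test", "CC", 0, 20, 185, 20e6, true_qm = 18.1,
                        seed = 11)
  r1 <- simulate_readings(spec, coarse_grid())
  r2 <- simulate_readings(spec, coarse_grid())
  expect_identical(r1, r2)
  spec2 <- spec; spec2$seed <- 12L
  expect_false(identical(simulate_readings(spec2, coarse_grid()), r1))
})

test_that("inverting noiseless preset readings recovers the preset truth", {
  presets <- preset_scenarios()
  spec <- presets$cc_20pct_20M_day0
  spec$noise_sd <- 0
  grid <- coarse_grid()
  readings <- simulate_readings(spec, grid)
  est <- fit_qm(readings$o2c_percent[1], grid, scenario_params(spec),
                scenario_density(spec))
  expect_equal(est$Q_m, spec$true_qm, tolerance = 0.01)
})

test_that("noise-free assays scale DNA by the growth ratio exactly", {
  spec <- scenario_spec("test", "BMSC", 24, 20, 185, 20e6, true_qm = 13.1,
                        dna_ratio_core = 1.4, dna_ratio_annulus = 1.4,
                        assay_cv = 0, n_replicates = 2, seed = 3)
  spec0 <- spec; spec0$day <- 0L; spec0$true_qm <- 43.2
  grid <- coarse_grid()
  a24 <- simulate_assays(spec, grid)
  a0 <- simulate_assays(spec0, grid)
  for (rg in c("core", "annulus")) {
    expect_equal(a24$dna_ug[a24$region == rg],
                 1.4 * a0$dna_ug[a0$region == rg])
  }
})

test_that("matrix deposition responds to regional oxygen as configured", {
  grid <- coarse_grid()
  # 20% arm, day 24: core is more hypoxic than the annulus -> more sGAG/volume
  spec <- scenario_spec("hi", "BMSC", 24, 20, 185, 20e6, true_qm = 13.1,
                        dna_ratio_core = 1.4, dna_ratio_annulus = 1.4,
                        assay_cv = 0, n_replicates = 1, seed = 5)
  a <- simulate_assays(spec, grid)
  dens <- a$sgag_ug / (a$wet_weight_mg * 1000)
  expect_gt(dens[a$region == "core"], dens[a$region == "annulus"])
  # 5% arm: the core mean drops below the 2% knee -> collagen suppressed there
  spec5 <- scenario_spec("lo", "BMSC", 24, 5, 50, 20e6, true_qm = 8.7,
                         dna_ratio_core = 1.4, dna_ratio_annulus = 1.4,
                         assay_cv = 0, n_replicates = 1, seed = 5)
  a5 <- simulate_assays(spec5, grid)
  cdens <- a5$hyp_ug * 7.69 / (a5$wet_weight_mg * 1000)
  expect_lt(cdens[a5$region == "core"], cdens[a5$region == "annulus"])
})

test_that("fixture bundles are reproducible and load end-to-end", {
  spec <- preset_scenarios(seed = 9)$cc_20pct_20M_day0
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  f1 <- write_fixture_bundle(spec, d1)
  f2 <- write_fixture_bundle(spec, d2)
  for (nm in names(f1)) {
    expect_identical(readBin(f1[[nm]], "raw", file.size(f1[[nm]])),
                     readBin(f2[[nm]], "raw", file.size(f2[[nm]])))
  }
  manifest <- yaml::read_yaml(f1[["manifest"]])
  expect_equal(manifest$seed, 9)
  # the bundle drives the pipeline end-to-end
  config <- read_scenario_config(f1[["config"]])
  config$solver$resolution_mm <- 0.5
  est <- run_fit(config, f1[["readings"]], quiet = TRUE)
  expect_true(all(is.na(est$error)))
  assays <- read_assay_samples(f1[["assays"]])
  expect_s3_class(normalize_biochem(assays), "data.frame")
})
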