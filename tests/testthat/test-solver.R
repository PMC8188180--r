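# Closed-form oracles for a 1-D slab with fixed concentration on top and a
# no-flux base: zero-order sink (c >> K_m) and first-order sink (c << K_m).
slab_zero_order <- function(x, c_top, R0, D, L) c_top - (R0 / D) * (L * x - x^2 / 2)
slab_first_order <- function(x, c_top, k, D, L) {
  c_top * cosh(sqrt(k / D) * (L - x)) / cosh(sqrt(k / D) * L)
}

test_that("zero consumption yields a uniform field at the surface value", {
  field <- solve_steady(coarse_grid(), default_params(), seeding_20M(), 0)
  expect_lt(max(abs(field$conc - 185)) / 185, 1e-10)
  expect_equal(central_o2(field), 20, tolerance = 1e-10)
  expect_lt(flux_balance(field), 1e-6)
})

test_that("solver matches the zero-order slab closed form within 1%", {
  L <- 1
  slab <- slab_grid(L, dz = 0.05)
  # K_m far below the field so the sink is effectively constant at saturation
  params <- model_parameters(K_m = 1e-3)
  rho <- 20e6; Q_m <- 27.7
  field <- solve_steady(slab, params, cell_density_map(rho), Q_m)
  R0 <- rho * Q_m * 1e-9   # uM/s at saturation
  x <- L - slab$z_centers  # depth below the fixed-concentration surface
  exact <- slab_zero_order(x, 185, R0, params$D_ag, L)
  expect_gt(min(exact), 50 * params$K_m)  # oracle regime c >> K_m holds
  expect_lt(max(abs(field$conc - exact) / exact), 0.01)
})

test_that("solver matches the first-order slab closed form within 1%", {
  L <- 1
  slab <- slab_grid(L, dz = 0.05)
  # K_m far above the field so the sink is effectively linear in c
  params <- model_parameters(K_m = 1e5)
  rho <- 20e6; Q_m <- 5.5e4
  field <- solve_steady(slab, params, cell_density_map(rho), Q_m)
  k <- rho * Q_m * 1e-9 / params$K_m   # 1/s
  x <- L - slab$z_centers
  exact <- slab_first_order(x, 185, k, params$D_ag, L)
  expect_lt(max(abs(field$conc - exact) / exact), 0.01)
})

test_that("converged solves conserve flux; truncated iterations do not", {
  field <- solve_steady(coarse_grid(), default_params(), seeding_20M(), 18.1)
  expect_lt(flux_balance(field), 1e-6)
  expect_lt(field$flux_imbalance, 1e-6)
  raw <- solve_steady(coarse_grid(), default_params(), seeding_20M(), 18.1,
                      max_iter = 1L, enforce_convergence = FALSE)
  expect_false(raw$converged)
  expect_gt(flux_balance(raw), 1e-3)
  expect_error(
    solve_steady(coarse_grid(), default_params(), seeding_20M(), 18.1,
                 max_iter = 1L),
    "did not converge")
})

test_that("the discrete maximum principle holds under random parameters", {
  set.seed(42)
  for (k in 1:20) {
    params <- model_parameters(
      C_surface = stats::runif(1, 20, 300),
      K_m = stats::runif(1, 1, 200),
      phi_f = stats::runif(1, 0.5, 1))
    rho <- stats::runif(1, 1e6, 6e7)
    Q_m <- stats::runif(1, 0, 80)
    field <- solve_steady(tiny_grid(), params, cell_density_map(rho), Q_m)
    expect_gte(min(field$conc), 0)
    expect_lte(max(field$conc), params$C_surface * (1 + 1e-12))
  }
})

test_that("central oxygen decreases strictly with the consumption rate", {
  qms <- seq(0, 60, by = 10)
  central <- vapply(qms, function(qm) {
    central_o2(solve_steady(tiny_grid(), default_params(), seeding_20M(), qm))
  }, numeric(1))
  expect_true(all(diff(central) < 0))
})

test_that("solves are deterministic for identical inputs", {
  f1 <- solve_steady(tiny_grid(), default_params(), seeding_20M(), 18.1)
  f2 <- solve_steady(tiny_grid(), default_params(), seeding_20M(), 18.1)
  expect_identical(f1$conc, f2$conc)
})

test_that("field sampling interpolates bilinearly with boundary clamping", {
  field <- solve_steady(coarse_grid(), default_params(), seeding_20M(), 0)
  expect_equal(unname(sample_at(field, 7.3, 4.1)["uM"]), 185,
               tolerance = 1e-10)
  # crafted two-cell slab: sampling at the shared face averages the centres
  slab <- slab_grid(0.5, dz = 0.25)
  f <- solve_steady(slab, default_params(), cell_density_map(0), 0)
  f$conc <- matrix(c(10, 30), 1, 2)
  zmid <- mean(slab$z_centers)
  expect_equal(unname(sample_at(f, 0.1, zmid)["uM"]), 20)
  expect_error(sample_at(field, 50, 1), "outside")
})

test_that("negative consumption rates and invalid densities are rejected", {
  expect_error(solve_steady(tiny_grid(), default_params(), seeding_20M(), -1),
               "non-negative")
  expect_error(cell_density_map(-5), "non-negative")
})
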