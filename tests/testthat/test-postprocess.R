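uniform_field <- function() {
  cached("uniform_field",
         solve_steady(coarse_grid(), default_params(), seeding_20M(), 0))
}

test_that("central oxygen of a uniform field is the surface level", {
  expect_equal(central_o2(uniform_field()), 20, tolerance = 1e-10)
})

test_that("region means are volume-weighted and bounded by the field", {
  f <- uniform_field()
  for (rg in c("construct_core", "construct_annulus", "media"))
    expect_equal(region_mean_o2(f, rg), 20, tolerance = 1e-10)
  expect_error(region_mean_o2(f, "nonexistent"), "not present")

  # independent direct-integration oracle on a consuming field
  f18 <- cached("coarse_field_18",
                solve_steady(coarse_grid(), default_params(), seeding_20M(),
                             18.1))
  g <- f18$grid
  m <- g$region == "construct_core"
  oracle <- sum(f18$conc[m] * g$volume[m]) / sum(g$volume[m]) /
    f18$params$uM_per_percent
  expect_equal(region_mean_o2(f18, "construct_core"), oracle,
               tolerance = 1e-10)
  expect_gte(region_mean_o2(f18, "construct_core"), min(f18$conc) / 9.25)
  expect_lte(region_mean_o2(f18, "construct_core"), max(f18$conc) / 9.25)
})

test_that("two equal-volume cells average to their midpoint", {
  slab <- slab_grid(0.5, dz = 0.25)
  f <- solve_steady(slab, default_params(), cell_density_map(0), 0)
  f$conc <- matrix(c(92.5, 277.5), 1, 2)  # 10% and 30%
  expect_equal(region_mean_o2(f, "construct_core"), 20)
})

test_that("a field increasing with radius puts the annulus above the core", {
  f <- uniform_field()
  f <- unclass(f)
  class(f) <- "concentration_field"
  f$conc <- matrix(rep(f$grid$r_centers, f$grid$nz), f$grid$nr, f$grid$nz)
  expect_gt(region_mean_o2(f, "construct_annulus"),
            region_mean_o2(f, "construct_core"))
})

test_that("oxygen frequency fractions are a partition of the region volume", {
  f <- uniform_field()
  freq <- o2_frequency(f, "construct_core")
  expect_equal(sum(freq$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(freq$fraction[freq$bin_lo <= 20 & freq$bin_hi >= 20]), 1)

  f18 <- cached("coarse_field_18",
                solve_steady(coarse_grid(), default_params(), seeding_20M(),
                             18.1))
  freq18 <- o2_frequency(f18, "construct_core")
  expect_true(all(freq18$fraction >= 0))
  expect_equal(sum(freq18$fraction), 1, tolerance = 1e-9)
  expect_error(o2_frequency(f, "construct_core", breaks = c(3, 2, 1)),
               "increasing")
  expect_error(o2_frequency(f, "construct_core", breaks = c(0, 10)),
               "cover")
})

test_that("two equal-volume cells in different bins split 50/50", {
  slab <- slab_grid(0.5, dz = 0.25)
  f <- solve_steady(slab, default_params(), cell_density_map(0), 0)
  f$conc <- matrix(c(9.25, 46.25), 1, 2)  # 1% and 5%
  freq <- o2_frequency(f, "construct_core", breaks = c(0, 2, 10))
  expect_equal(freq$fraction, c(0.5, 0.5))
})

test_that("the low-external-oxygen arm develops a hypoxic construct", {
  params <- model_parameters(C_surface = 50)
  # day 24: region means land near the reported 1.7% (core) and 2.3% (annulus)
  f24 <- solve_steady(coarse_grid(), params, cell_density_map(28e6, day = 24),
                      8.7)
  expect_lt(abs(region_mean_o2(f24, "construct_core") - 1.7), 0.7)
  expect_lt(abs(region_mean_o2(f24, "construct_annulus") - 2.3), 0.7)
  # day 0 (higher consumption): most of the construct volume sits below 2%
  f0 <- solve_steady(coarse_grid(), params, cell_density_map(20e6), 43.2)
  summ <- oxygen_summary(f0, hypoxia_threshold = 2)
  construct_frac <-
    (summ$fraction_below[["construct_core"]] *
       region_volume(f0$grid, "construct_core") +
     summ$fraction_below[["construct_annulus"]] *
       region_volume(f0$grid, "construct_annulus")) /
    (region_volume(f0$grid, "construct_core") +
       region_volume(f0$grid, "construct_annulus"))
  expect_gt(construct_frac, 0.5)
})

test_that("contour export round-trips and is byte-stable", {
  f <- uniform_field()
  p1 <- file.path(tempdir(), "field1.tsv")
  p2 <- file.path(tempdir(), "field2.tsv")
  export_contour(f, p1)
  export_contour(f, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_contour(p1)
  expect_equal(nrow(back), f$grid$nr * f$grid$nz)
  expect_equal(back$c_uM, c(f$conc), tolerance = 1e-11)
  expect_equal(back$region, c(f$grid$region))
})
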