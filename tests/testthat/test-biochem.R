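assay_row <- function(sample_id = "s1", day = 24, region = "whole",
                      ww = 10, dna = 2, sgag = 175, hyp = 5) {
  data.frame(sample_id = sample_id, day = day, region = region,
             wet_weight_mg = ww, dna_ug = dna, sgag_ug = sgag, hyp_ug = hyp)
}

test_that("hydroxyproline converts to collagen at the 1:7.69 ratio", {
  expect_equal(collagen_from_hydroxyproline(1.0), 7.69)
  expect_equal(collagen_from_hydroxyproline(0), 0)
  expect_equal(collagen_from_hydroxyproline(13.0), 99.97)
  expect_error(collagen_from_hydroxyproline(-1), "non-negative")
})

test_that("biochemical normalisation computes per-DNA and wet-weight ratios", {
  out <- normalize_biochem(assay_row())
  expect_equal(out$sgag_percent_ww, 1.75)            # 175 ug in 10 mg
  expect_equal(out$collagen_per_dna, 5 * 7.69 / 2)   # 19.225
  expect_equal(out$sgag_per_dna, 87.5)
  zero <- normalize_biochem(assay_row(sgag = 0, hyp = 0))
  expect_equal(zero$sgag_percent_ww, 0)
  expect_equal(zero$collagen_per_dna, 0)
})

test_that("zero DNA or wet weight flags metrics as undefined, not zero", {
  expect_warning(out <- normalize_biochem(assay_row(dna = 0)), "zero DNA")
  expect_true(is.na(out$sgag_per_dna))
  expect_false(is.na(out$sgag_percent_ww))
  expect_warning(out2 <- normalize_biochem(assay_row(ww = 0)), "wet weight")
  expect_true(is.na(out2$sgag_percent_ww))
})

test_that("normalisation is invariant to consistent mass rescaling", {
  a <- normalize_biochem(assay_row())
  b <- normalize_biochem(assay_row(dna = 2 * 3, sgag = 175 * 3, hyp = 5 * 3))
  expect_equal(a$sgag_per_dna, b$sgag_per_dna)
  expect_equal(a$collagen_per_dna, b$collagen_per_dna)
})

test_that("density updates scale the seeding density by the DNA ratio", {
  expect_equal(update_density(1.4, 1.0, 20e6), 28e6)  # ~40% DNA increase
  expect_equal(update_density(1.0, 1.0, 20e6), 20e6)
  expect_equal(update_density(0.8, 1.0, 20e6), 16e6)  # ~20% DNA decrease
  expect_error(update_density(1, 0, 20e6), "positive")
  # linear in both arguments
  expect_equal(update_density(2.8, 1.0, 20e6), 2 * update_density(1.4, 1, 20e6))
  expect_equal(update_density(1.4, 1.0, 40e6), 2 * update_density(1.4, 1, 20e6))
})

test_that("density maps come from region-wise day-24/day-0 DNA ratios", {
  assays <- rbind(
    assay_row("d0c", day = 0, region = "core", dna = 1.0),
    assay_row("d0a", day = 0, region = "annulus", dna = 2.0),
    assay_row("d24c", day = 24, region = "core", dna = 1.4),
    assay_row("d24a", day = 24, region = "annulus", dna = 2.8))
  dm <- build_density_map(assays, rho0 = 20e6, day = 24)
  expect_equal(dm$construct_core, 28e6)
  expect_equal(dm$construct_annulus, 28e6)
  expect_equal(dm$agarose_bed, 0)
  expect_equal(dm$day, 24)
})

test_that("whole-construct day-0 baselines are split by region volume", {
  geom <- construct_geometry()
  frac_core <- geom$core_radius^2 / geom$construct_radius^2
  assays <- rbind(
    assay_row("d0", day = 0, region = "whole", dna = 10),
    assay_row("d24c", day = 24, region = "core", dna = 10 * frac_core),
    assay_row("d24a", day = 24, region = "annulus", dna = 10 * (1 - frac_core)))
  dm <- build_density_map(assays, rho0 = 20e6, day = 24)
  expect_equal(dm$construct_core, 20e6)
  expect_equal(dm$construct_annulus, 20e6)
})

test_that("day-0 maps are uniform and missing regions are an error", {
  dm <- build_density_map(data.frame(), rho0 = 20e6, day = 0)
  expect_equal(dm$construct_core, 20e6)
  expect_equal(dm$construct_annulus, 20e6)
  assays <- rbind(assay_row("d0", day = 0, region = "whole", dna = 10),
                  assay_row("d24c", day = 24, region = "core", dna = 4))
  expect_error(build_density_map(assays, 20e6, day = 24), "annulus")
})
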