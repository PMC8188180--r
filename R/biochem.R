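#' Convert hydroxyproline mass to total collagen mass
#'
#' Collagen content is assayed via its hydroxyproline; total collagen is
#' obtained with a hydroxyproline:collagen mass ratio of 1:7.69.
#'
#' @param hyp Hydroxyproline mass (ug), non-negative; vectorised.
#' @return Collagen mass (ug), `7.69 * hyp`.
#' @examples
#' collagen_from_hydroxyproline(1)   # 7.69
#' @export
collagen_from_hydroxyproline <- function(hyp) {
  if (any(hyp < 0, na.rm = TRUE)) stop("hydroxyproline mass must be non-negative")
  7.69 * hyp
}

#' Normalise biochemical assay readouts per sample
#'
#' Computes the standard matrix-accumulation metrics from raw per-sample
#' assay masses: sGAG and collagen normalised to DNA (ug/ug) and expressed as
#' a percentage of tissue wet weight (%ww, mass percent with the wet weight
#' converted from mg to ug). Collagen is derived from hydroxyproline with
#' [collagen_from_hydroxyproline()].
#'
#' Samples with zero DNA or zero wet weight get `NA` for the affected metrics
#' (with a warning) rather than a silent zero.
#'
#' @param samples Data frame with columns `sample_id`, `day`, `region`
#'   (`core`, `annulus` or `whole`), `wet_weight_mg`, `dna_ug`, `sgag_ug`,
#'   `hyp_ug`.
#' @return The input with added columns `collagen_ug`, `sgag_per_dna`,
#'   `collagen_per_dna`, `sgag_percent_ww`, `collagen_percent_ww`.
#' @examples
#' s <- data.frame(sample_id = "a", day = 24, region = "whole",
#'                 wet_weight_mg = 10, dna_ug = 2, sgag_ug = 175, hyp_ug = 5)
#' normalize_biochem(s)$sgag_percent_ww  # 1.75 %ww
#' @export
normalize_biochem <- function(samples) {
  req <- c("sample_id", "day", "region", "wet_weight_mg", "dna_ug",
           "sgag_ug", "hyp_ug")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stop("samples must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (!all(samples$region %in% c("core", "annulus", "whole")))
    stop("region must be one of 'core', 'annulus', 'whole'")
  num <- c("wet_weight_mg", "dna_ug", "sgag_ug", "hyp_ug")
  if (any(as.matrix(samples[num]) < 0, na.rm = TRUE))
    stop("assay masses must be non-negative")
  out <- samples
  out$collagen_ug <- collagen_from_hydroxyproline(samples$hyp_ug)
  dna <- ifelse(samples$dna_ug > 0, samples$dna_ug, NA_real_)
  ww_ug <- ifelse(samples$wet_weight_mg > 0,
                  samples$wet_weight_mg * 1000, NA_real_)
  if (anyNA(dna)) warning("zero DNA in some samples; per-DNA metrics set NA")
  if (anyNA(ww_ug)) warning("zero wet weight in some samples; %ww metrics set NA")
  out$sgag_per_dna <- samples$sgag_ug / dna
  out$collagen_per_dna <- out$collagen_ug / dna
  out$sgag_percent_ww <- 100 * samples$sgag_ug / ww_ug
  out$collagen_percent_ww <- 100 * out$collagen_ug / ww_ug
  out
}

#' Update a cell density from the day-24/day-0 DNA ratio
#'
#' Cell densities for day-24 models are obtained by scaling the seeding
#' density by the ratio of a sample's day-24 DNA content to the mean day-0
#' DNA content: `rho = (dna_day24 / mean_dna_day0) * rho0`.
#'
#' @param dna_day24 Day-24 DNA mass (ug), non-negative; vectorised.
#' @param mean_dna_day0 Mean day-0 DNA mass (ug), positive.
#' @param rho0 Initial seeding density (cells/mL).
#' @return Updated cell density (cells/mL).
#' @examples
#' update_density(1.4, 1.0, 20e6)  # 28e6: a 40% DNA increase
#' @export
update_density <- function(dna_day24, mean_dna_day0, rho0) {
  if (any(dna_day24 < 0)) stop("dna_day24 must be non-negative")
  if (!is.numeric(mean_dna_day0) || mean_dna_day0 <= 0)
    stop("mean day-0 DNA must be positive")
  if (rho0 < 0) stop("rho0 must be non-negative")
  (dna_day24 / mean_dna_day0) * rho0
}

#' Build a day-24 cell density map from assay tables
#'
#' Computes region-wise day-24 cell densities from DNA assays: for the core
#' and the annulus separately, the mean day-24 DNA is normalised to the mean
#' day-0 DNA of the matching region and multiplied by the seeding density.
#' When no day-0 samples exist for a region, the whole-construct day-0 mean
#' is scaled by the region's volume fraction of the construct. A `day = 0`
#' request returns the uniform seeding-density map.
#'
#' @param assays Assay data frame as in [normalize_biochem()], containing
#'   `core` and `annulus` rows for the requested day and day-0 baseline rows
#'   (region-matched, or `whole`).
#' @param rho0 Seeding density (cells/mL).
#' @param day Day of the requested map (0 returns the uniform map).
#' @param geometry A [construct_geometry()], used only for the core/annulus
#'   volume split when the day-0 baseline has `whole`-construct rows.
#' @return A [cell_density_map()].
#' @export
build_density_map <- function(assays, rho0, day = 24,
                              geometry = construct_geometry()) {
  if (day == 0) return(cell_density_map(rho0, rho0, day = 0))
  req <- c("sample_id", "day", "region", "dna_ug")
  if (!is.data.frame(assays) || !all(req %in% names(assays)))
    stop("assays must be a data frame with at least columns ",
         paste(req, collapse = ", "))
  vol_core <- pi * geometry$core_radius^2 * geometry$construct_height
  vol_total <- pi * geometry$construct_radius^2 * geometry$construct_height
  frac <- c(core = vol_core / vol_total, annulus = 1 - vol_core / vol_total)
  day0 <- assays[assays$day == 0, ]
  baseline <- function(region) {
    matched <- day0$dna_ug[day0$region == region]
    if (length(matched) > 0L) return(mean(matched))
    whole <- day0$dna_ug[day0$region == "whole"]
    if (length(whole) > 0L) return(mean(whole) * frac[[region]])
    stop("no day-0 baseline DNA for region '", region, "'")
  }
  rho_for <- function(region) {
    d <- assays$dna_ug[assays$day == day & assays$region == region]
    if (length(d) == 0L)
      stop("no day-", day, " samples for region '", region, "'")
    update_density(mean(d), baseline(region), rho0)
  }
  cell_density_map(rho_for("core"), rho_for("annulus"), day = day)
}
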