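#' Predicted oxygen level at the construct's geometric centre
#'
#' Samples the solved field at the sensor position (on the axis, at the
#' construct's mid-height) and converts to % O2.
#'
#' @param field A [solve_steady()] result on a geometry-based grid.
#' @return Central oxygen level (% O2).
#' @export
central_o2 <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  if (is.null(field$grid$geometry))
    stop("central_o2 needs a field solved on a construct geometry")
  sens <- sensor_position(field$grid$geometry)
  unname(sample_at(field, sens["r"], sens["z"])["percent"])
}

#' Volume-weighted mean oxygen level of a region
#'
#' @param field A [solve_steady()] result.
#' @param region Region label (`construct_core`, `construct_annulus`,
#'   `agarose_bed` or `media`).
#' @return Mean oxygen level of the region (% O2), weighted by cell volume.
#' @export
region_mean_o2 <- function(field, region) {
  stopifnot(inherits(field, "concentration_field"))
  g <- field$grid
  m <- g$region == region
  if (!any(m)) stop("region '", region, "' not present in this grid")
  conc_to_percent(sum(field$conc[m] * g$volume[m]) / sum(g$volume[m]),
                  field$params$uM_per_percent)
}

#' Volumetric oxygen frequency distribution of a region
#'
#' Fraction of a region's volume at each oxygen level: bins are half-open
#' `[lo, hi)` with the final bin closed, and fractions sum to one over the
#' region.
#'
#' @param field A [solve_steady()] result.
#' @param region Region label.
#' @param breaks Increasing bin edges (% O2) covering the region's oxygen
#'   range; defaults to 0.5%-wide bins from 0 to the nominal external level.
#' @return Data frame with `bin_lo`, `bin_hi`, `fraction`.
#' @export
o2_frequency <- function(field, region = "construct_core", breaks = NULL) {
  stopifnot(inherits(field, "concentration_field"))
  g <- field$grid
  m <- g$region == region
  if (!any(m)) stop("region '", region, "' not present in this grid")
  pct <- conc_to_percent(field$conc[m], field$params$uM_per_percent)
  if (is.null(breaks)) {
    top <- conc_to_percent(field$params$C_surface, field$params$uM_per_percent)
    breaks <- seq(0, ceiling(top / 0.5) * 0.5, by = 0.5)
  }
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  last <- breaks[length(breaks)]
  tol <- 1e-9 * max(abs(last), 1)
  if (min(pct) < breaks[1L] - tol || max(pct) > last + tol)
    stop("breaks must cover the region's oxygen range [",
         signif(min(pct), 3), ", ", signif(max(pct), 3), "] % O2")
  pct <- pmin(pmax(pct, breaks[1L]), last)
  k <- findInterval(pct, breaks, rightmost.closed = TRUE, left.open = FALSE)
  vol <- g$volume[m]
  frac <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(vol[k == b]), numeric(1)) / sum(vol)
  data.frame(bin_lo = utils::head(breaks, -1L),
             bin_hi = utils::tail(breaks, -1L),
             fraction = frac)
}

#' Summary statistics of a solved oxygen field
#'
#' Collects the reported spatial oxygen analytics in one object: the central
#' oxygen level, volume-weighted mean per construct region, the volume
#' fraction of each region below a hypoxia threshold, and the volumetric
#' frequency histogram over the whole construct.
#'
#' @param field A [solve_steady()] result on a geometry-based grid.
#' @param hypoxia_threshold Oxygen level (% O2) defining the reported
#'   low-oxygen volume fractions.
#' @param breaks Histogram bin edges (% O2), as in [o2_frequency()].
#' @return An object of class `"oxygen_summary"` with elements `central_o2`,
#'   `region_means` (named, % O2), `fraction_below` (named), `histogram`
#'   (whole-construct data frame) and the `Q_m` and day tag of the solve.
#' @export
oxygen_summary <- function(field, hypoxia_threshold = 2, breaks = NULL) {
  stopifnot(inherits(field, "concentration_field"))
  g <- field$grid
  regions <- c("construct_core", "construct_annulus")
  means <- vapply(regions, function(rg) region_mean_o2(field, rg), numeric(1))
  frac_below <- vapply(regions, function(rg) {
    m <- g$region == rg
    pct <- conc_to_percent(field$conc[m], field$params$uM_per_percent)
    sum(g$volume[m][pct < hypoxia_threshold]) / sum(g$volume[m])
  }, numeric(1))
  construct <- g$region %in% regions
  pct <- conc_to_percent(field$conc[construct], field$params$uM_per_percent)
  vol <- g$volume[construct]
  if (is.null(breaks)) {
    top <- conc_to_percent(field$params$C_surface, field$params$uM_per_percent)
    breaks <- seq(0, ceiling(top / 0.5) * 0.5, by = 0.5)
  }
  pct <- pmin(pmax(pct, breaks[1L]), breaks[length(breaks)])
  k <- findInterval(pct, breaks, rightmost.closed = TRUE, left.open = FALSE)
  frac <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(vol[k == b]), numeric(1)) / sum(vol)
  structure(list(central_o2 = central_o2(field),
                 region_means = means,
                 fraction_below = frac_below,
                 hypoxia_threshold = hypoxia_threshold,
                 histogram = data.frame(bin_lo = utils::head(breaks, -1L),
                                        bin_hi = utils::tail(breaks, -1L),
                                        fraction = frac),
                 Q_m = field$Q_m, day = field$density_map$day),
            class = "oxygen_summary")
}

#' @export
print.oxygen_summary <- function(x, ...) {
  cat(sprintf("Oxygen summary (Q_m = %.4g amol/cell/s, day %s)\n",
              x$Q_m, format(x$day)))
  cat(sprintf("  central O2          %.2f %%\n", x$central_o2))
  cat(sprintf("  core mean / annulus %.2f / %.2f %%\n",
              x$region_means[["construct_core"]],
              x$region_means[["construct_annulus"]]))
  cat(sprintf("  volume below %.3g%%: core %.0f%%, annulus %.0f%%\n",
              x$hypoxia_threshold,
              100 * x$fraction_below[["construct_core"]],
              100 * x$fraction_below[["construct_annulus"]]))
  invisible(x)
}

#' Export a solved field as a contour-ready delimited table
#'
#' Writes one row per grid cell with columns `r_mm`, `z_mm`, `region`, `c_uM`,
#' `o2_percent` (tab-separated, 12 significant digits), suitable for external
#' contour rendering. Output is byte-stable for identical runs on the same
#' platform.
#'
#' @param field A [solve_steady()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_contour <- function(field, path) {
  stopifnot(inherits(field, "concentration_field"))
  g <- field$grid
  df <- data.frame(
    r_mm = rep(g$r_centers, times = g$nz),
    z_mm = rep(g$z_centers, each = g$nr),
    region = c(g$region),
    c_uM = c(field$conc),
    o2_percent = conc_to_percent(c(field$conc), field$params$uM_per_percent))
  num <- c("r_mm", "z_mm", "c_uM", "o2_percent")
  for (nm in num) df[[nm]] <- sprintf("%.12g", df[[nm]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

#' @rdname export_contour
#' @return `read_contour` returns the exported table as a data frame with
#'   numeric columns restored.
#' @export
read_contour <- function(path) {
  utils::read.delim(path, colClasses = c(r_mm = "numeric", z_mm = "numeric",
                                         region = "character",
                                         c_uM = "numeric",
                                         o2_percent = "numeric"))
}
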