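#' Geometry of the test dish and construct
#'
#' Describes the axisymmetric culture setup: a cylindrical construct sitting in
#' a recess of an acellular agarose bed at the centre of a culture dish, with
#' medium filling the dish above the bed and covering the construct. The
#' coordinate system is cylindrical (r, z) with z = 0 at the dish base and z
#' increasing upward; all material interfaces are axis-aligned.
#'
#' Defaults describe a 5 mm diameter x 3 mm construct in a 60 mm dish with a
#' 3 mm agarose bed, a 1.5 mm deep recess of the construct's diameter, and a
#' 1 mm layer of medium above the construct. The core radius (1.5 mm) is the
#' biopsy-punch radius used to split each construct into a core and an annulus
#' for region-wise analysis.
#'
#' @param construct_radius Construct radius (mm).
#' @param construct_height Construct height (mm).
#' @param core_radius Radius of the biopsy-punch core region (mm).
#' @param dish_radius Dish radius (mm).
#' @param bed_depth Depth of the acellular agarose bed (mm).
#' @param recess_depth Depth of the recess holding the construct (mm).
#' @param media_depth Depth of medium above the construct top (mm).
#'
#' @return An object of class `"construct_geometry"`.
#' @examples
#' geom <- construct_geometry()
#' sensor_position(geom)  # r = 0, z at the construct's geometric centre
#' @export
construct_geometry <- function(construct_radius = 2.5,
                               construct_height = 3.0,
                               core_radius = 1.5,
                               dish_radius = 30.0,
                               bed_depth = 3.0,
                               recess_depth = 1.5,
                               media_depth = 1.0) {
  g <- list(construct_radius = construct_radius,
            construct_height = construct_height,
            core_radius = core_radius,
            dish_radius = dish_radius,
            bed_depth = bed_depth,
            recess_depth = recess_depth,
            media_depth = media_depth)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("geometry field '", nm, "' must be a single positive length (mm)")
  }
  if (!(core_radius < construct_radius && construct_radius < dish_radius))
    stop("require 0 < core_radius < construct_radius < dish_radius")
  if (recess_depth >= bed_depth)
    stop("recess_depth must be smaller than bed_depth")
  g$construct_base <- bed_depth - recess_depth
  g$construct_top <- g$construct_base + construct_height
  g$media_surface <- g$construct_top + media_depth
  structure(g, class = "construct_geometry")
}

#' @export
print.construct_geometry <- function(x, ...) {
  cat("Axisymmetric dish-bed-construct-media geometry (mm)\n")
  cat(sprintf("  construct  r < %.3g, %.3g <= z <= %.3g (core r < %.3g)\n",
              x$construct_radius, x$construct_base, x$construct_top,
              x$core_radius))
  cat(sprintf("  dish r = %.3g, bed depth %.3g, recess %.3g, media surface z = %.3g\n",
              x$dish_radius, x$bed_depth, x$recess_depth, x$media_surface))
  invisible(x)
}

#' @rdname construct_geometry
#' @param geometry A `construct_geometry`.
#' @return `sensor_position` returns the sensor location, a named numeric
#'   vector `c(r = 0, z = ...)` at the geometric centre of the construct.
#' @export
sensor_position <- function(geometry) {
  stopifnot(inherits(geometry, "construct_geometry"))
  c(r = 0, z = geometry$construct_base + geometry$construct_height / 2)
}

# Nodes covering consecutive segments so every break lands on a grid line;
# spacing within each segment is adjusted to at most `h`.
segment_nodes <- function(breaks, h) {
  out <- breaks[1L]
  for (k in seq_len(length(breaks) - 1L)) {
    len <- breaks[k + 1L] - breaks[k]
    n <- max(1L, ceiling(len / h - 1e-9))
    out <- c(out, breaks[k] + len * seq_len(n) / n)
  }
  out
}

#' Build the labelled axisymmetric finite-volume grid
#'
#' Discretises the dish domain on a structured tensor-product (r, z) grid.
#' Material and region interfaces land exactly on grid lines (the spacing is
#' adjusted per segment), every cell carries one region label in
#' `construct_core`, `construct_annulus`, `agarose_bed`, `media`, and the cell
#' volume is the exact revolved volume `2*pi*rbar*dr*dz`.
#'
#' @param geometry A [construct_geometry()].
#' @param resolution Target grid spacing (mm); must be positive and no larger
#'   than the smallest geometric feature.
#' @return An object of class `"axi_grid"` with node coordinates, cell centres
#'   and widths, the region label matrix (`nr` x `nz`) and cell volumes (mm^3).
#' @examples
#' grid <- build_domain(construct_geometry(), resolution = 0.25)
#' region_volume(grid, "construct_core")  # ~ pi * 1.5^2 * 3
#' @export
build_domain <- function(geometry, resolution = 0.1) {
  stopifnot(inherits(geometry, "construct_geometry"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive spacing in mm")
  r_breaks <- c(0, geometry$core_radius, geometry$construct_radius,
                geometry$dish_radius)
  z_breaks <- c(0, geometry$construct_base, geometry$bed_depth,
                geometry$construct_top, geometry$media_surface)
  feat <- min(diff(r_breaks), diff(z_breaks))
  if (resolution > feat + 1e-12)
    stop("resolution (", resolution, " mm) exceeds the smallest geometric ",
         "feature (", signif(feat, 3), " mm)")
  r_nodes <- segment_nodes(r_breaks, resolution)
  z_nodes <- segment_nodes(z_breaks, resolution)
  rc <- (utils::head(r_nodes, -1L) + utils::tail(r_nodes, -1L)) / 2
  zc <- (utils::head(z_nodes, -1L) + utils::tail(z_nodes, -1L)) / 2
  dr <- diff(r_nodes)
  dz <- diff(z_nodes)
  nr <- length(rc)
  nz <- length(zc)
  R <- matrix(rc, nr, nz)
  Z <- matrix(zc, nr, nz, byrow = TRUE)
  region <- matrix("media", nr, nz)
  in_construct <- R < geometry$construct_radius &
    Z > geometry$construct_base & Z < geometry$construct_top
  region[in_construct & R < geometry$core_radius] <- "construct_core"
  region[in_construct & R >= geometry$core_radius] <- "construct_annulus"
  region[Z < geometry$construct_base |
           (Z < geometry$bed_depth & !in_construct)] <- "agarose_bed"
  volume <- outer(2 * pi * rc * dr, dz)
  structure(list(r_nodes = r_nodes, z_nodes = z_nodes,
                 r_centers = rc, z_centers = zc, dr = dr, dz = dz,
                 nr = nr, nz = nz, region = region, volume = volume,
                 geometry = geometry, resolution = resolution),
            class = "axi_grid")
}

#' @export
print.axi_grid <- function(x, ...) {
  cat(sprintf("Axisymmetric grid: %d x %d cells (target spacing %.3g mm)\n",
              x$nr, x$nz, x$resolution))
  tab <- table(x$region)
  for (nm in names(tab))
    cat(sprintf("  %-18s %6d cells, %9.3f mm^3\n", nm, tab[[nm]],
                region_volume(x, nm)))
  invisible(x)
}

#' Total volume of a labelled region
#'
#' @param grid An [build_domain()] grid.
#' @param label Region label present in the grid.
#' @return Region volume in mm^3 (sum of member cell volumes).
#' @export
region_volume <- function(grid, label) {
  stopifnot(inherits(grid, "axi_grid"))
  if (!label %in% grid$region)
    stop("region '", label, "' not present in this grid")
  sum(grid$volume[grid$region == label])
}

#' Locate the grid cell containing a point
#'
#' Cells are half-open, lower-inclusive intervals in both coordinates (the
#' outermost cell is closed), so a point lying exactly on an interior grid
#' line belongs to the cell whose lower edge it is.
#'
#' @param grid An [build_domain()] grid.
#' @param r,z Point coordinates (mm); must lie inside the domain.
#' @return A list with the radial/axial cell indices `i`, `j`, the linear
#'   index `cell`, and the cell's `region` label.
#' @export
locate_point <- function(grid, r, z) {
  stopifnot(inherits(grid, "axi_grid"))
  rn <- grid$r_nodes; zn <- grid$z_nodes
  if (r < rn[1L] || r > rn[length(rn)] || z < zn[1L] || z > zn[length(zn)])
    stop("point (", r, ", ", z, ") lies outside the domain")
  i <- min(findInterval(r, rn, left.open = FALSE), grid$nr)
  j <- min(findInterval(z, zn, left.open = FALSE), grid$nz)
  list(i = i, j = j, cell = i + (j - 1L) * grid$nr,
       region = grid$region[i, j])
}
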