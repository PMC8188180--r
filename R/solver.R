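#' Region-wise cell density map
#'
#' Cell densities assigned to the construct's core and annulus regions at a
#' given culture day. The acellular agarose bed and the medium always carry
#' zero density. Day-0 maps are uniform (seeding density in both regions);
#' day-24 maps typically carry separate core/annulus densities derived from
#' DNA assays (see [build_density_map()]).
#'
#' @param core Cell density in the construct core (cells/mL).
#' @param annulus Cell density in the construct annulus (cells/mL); defaults
#'   to `core`, giving a uniform map.
#' @param day Culture day tag (informational).
#' @return An object of class `"cell_density_map"`.
#' @examples
#' cell_density_map(20e6)                   # uniform day-0 seeding
#' cell_density_map(28e6, 26e6, day = 24)   # region-wise day-24 map
#' @export
cell_density_map <- function(core, annulus = core, day = 0) {
  if (!is.numeric(core) || !is.numeric(annulus) || core < 0 || annulus < 0)
    stop("cell densities must be non-negative (cells/mL)")
  structure(list(construct_core = core, construct_annulus = annulus,
                 agarose_bed = 0, media = 0, day = day),
            class = "cell_density_map")
}

#' @export
print.cell_density_map <- function(x, ...) {
  cat(sprintf("Cell density map (day %s): core %.3g, annulus %.3g cells/mL\n",
              format(x$day), x$construct_core, x$construct_annulus))
  invisible(x)
}

# Map region-wise densities onto grid cells (cells/mL, matrix nr x nz).
density_on_grid <- function(grid, density_map) {
  stopifnot(inherits(grid, "axi_grid"), inherits(density_map, "cell_density_map"))
  vals <- unlist(density_map[c("construct_core", "construct_annulus",
                               "agarose_bed", "media")])
  matrix(vals[grid$region], grid$nr, grid$nz)
}

# Assemble the constant (diffusive + Dirichlet) part of the finite-volume
# system once; the Michaelis-Menten sink only perturbs the diagonal, so Picard
# iterations and repeated Q_m evaluations reuse this context and the symbolic
# Cholesky factorisation.
fv_context <- function(grid, params, density_map) {
  nr <- grid$nr; nz <- grid$nz; n <- nr * nz
  rc <- grid$r_centers; dr <- grid$dr; dz <- grid$dz
  Dmat <- matrix(ifelse(grid$region == "media", params$D_media, params$D_ag),
                 nr, nz)
  idx <- matrix(seq_len(n), nr, nz)
  diag0 <- numeric(n)
  b0 <- numeric(n)
  pp <- qq <- ww <- list()

  if (nr > 1L) {
    # interior radial faces at r = r_nodes[i+1], between cells (i, j), (i+1, j)
    rf <- grid$r_nodes[2:nr]
    Af <- 2 * pi * outer(rf, dz)
    d1 <- matrix(dr[-nr] / 2, nr - 1L, nz)
    d2 <- matrix(dr[-1L] / 2, nr - 1L, nz)
    Df <- (d1 + d2) / (d1 / Dmat[-nr, , drop = FALSE] +
                         d2 / Dmat[-1L, , drop = FALSE])
    w <- Df * Af / (d1 + d2)
    p <- c(idx[-nr, , drop = FALSE]); q <- c(idx[-1L, , drop = FALSE])
    diag0[p] <- diag0[p] + c(w)
    diag0[q] <- diag0[q] + c(w)
    pp <- c(pp, list(p)); qq <- c(qq, list(q)); ww <- c(ww, list(c(w)))
  }
  if (nz > 1L) {
    # interior axial faces between cells (i, j), (i, j+1)
    Af <- matrix(2 * pi * rc * dr, nr, nz - 1L)
    d1 <- matrix(dz[-nz] / 2, nr, nz - 1L, byrow = TRUE)
    d2 <- matrix(dz[-1L] / 2, nr, nz - 1L, byrow = TRUE)
    Df <- (d1 + d2) / (d1 / Dmat[, -nz, drop = FALSE] +
                         d2 / Dmat[, -1L, drop = FALSE])
    w <- Df * Af / (d1 + d2)
    p <- c(idx[, -nz, drop = FALSE]); q <- c(idx[, -1L, drop = FALSE])
    diag0[p] <- diag0[p] + c(w)
    diag0[q] <- diag0[q] + c(w)
    pp <- c(pp, list(p)); qq <- c(qq, list(q)); ww <- c(ww, list(c(w)))
  }
  # top boundary: Dirichlet c = C_surface at the free medium surface;
  # all other boundaries (axis, dish wall, dish base) are zero-flux.
  w_top <- Dmat[, nz] * (2 * pi * rc * dr) / (dz[nz] / 2)
  top_cells <- idx[, nz]
  diag0[top_cells] <- diag0[top_cells] + w_top
  b0[top_cells] <- b0[top_cells] + w_top * params$C_surface

  Aoff <- Matrix::sparseMatrix(i = unlist(pp), j = unlist(qq),
                               x = -unlist(ww), dims = c(n, n),
                               symmetric = TRUE)
  rho <- density_on_grid(grid, density_map)
  # sink density at saturation, expressed in uM/s (1 uM = 1e-12 mol/mm^3)
  sink_sat_per_qm <- c(volumetric_sink(1, rho)) / 1e-12
  list(grid = grid, params = params, density_map = density_map,
       n = n, Aoff = Aoff, diag0 = diag0, b0 = b0,
       w_top = w_top, top_cells = top_cells,
       vol = c(grid$volume), sink_sat_per_qm = sink_sat_per_qm,
       chol = NULL)
}

# One nonlinear solve on a prepared context. Returns list(conc, iterations,
# max_change, flux_imbalance, converged) plus the updated context (cached
# Cholesky). Picard lags the Michaelis-Menten denominator, giving a linear
# M-matrix system each pass; iterates are clamped at zero inside the sink so
# intermediate undershoots cannot turn the sink into a source.
fv_solve <- function(ctx, Q_m, init = NULL, tol_change = 1e-8,
                     tol_flux = 1e-6, max_iter = 500L) {
  n <- ctx$n
  K_m <- ctx$params$K_m
  C_s <- ctx$params$C_surface
  sink_sat <- ctx$sink_sat_per_qm * Q_m          # uM/s at full saturation
  cvec <- if (is.null(init)) rep(C_s, n) else pmin(pmax(init, 0), C_s)
  converged <- FALSE
  imb <- NA_real_
  del <- NA_real_
  it <- 0L
  for (it in seq_len(max_iter)) {
    coef <- sink_sat / (K_m + pmax(cvec, 0)) * ctx$vol
    A <- ctx$Aoff + Matrix::Diagonal(n, ctx$diag0 + coef)
    A <- methods::as(Matrix::forceSymmetric(A), "CsparseMatrix")
    if (is.null(ctx$chol)) {
      ctx$chol <- Matrix::Cholesky(A, LDL = FALSE)
    } else {
      ctx$chol <- Matrix::update(ctx$chol, A)
    }
    cnew <- as.numeric(Matrix::solve(ctx$chol, ctx$b0))
    del <- max(abs(cnew - cvec)) / C_s
    cvec <- cnew
    if (del < tol_change) {
      imb <- fv_imbalance(ctx, cvec, Q_m)
      if (imb < tol_flux) {
        converged <- TRUE
        break
      }
    }
  }
  if (is.na(imb)) imb <- fv_imbalance(ctx, cvec, Q_m)
  list(conc = cvec, iterations = it, max_change = del,
       flux_imbalance = imb, converged = converged, ctx = ctx)
}

# Relative discrete flux imbalance: |top influx - integrated MM consumption|
# over max(influx, consumption, eps). The floor eps is a fixed tiny fraction
# of the boundary's total exchange capacity, so the zero-consumption case
# (influx and consumption both zero up to roundoff) reports ~0 instead of
# dividing roundoff by roundoff.
fv_imbalance <- function(ctx, cvec, Q_m) {
  influx <- sum(ctx$w_top * (ctx$params$C_surface - cvec[ctx$top_cells]))
  cons <- sum(ctx$sink_sat_per_qm * Q_m *
                pmax(cvec, 0) / (ctx$params$K_m + pmax(cvec, 0)) * ctx$vol)
  floor_eps <- 1e-6 * sum(ctx$w_top) * ctx$params$C_surface
  abs(influx - cons) / max(influx, cons, floor_eps)
}

#' Solve the steady oxygen diffusion-reaction equation
#'
#' Solves `0 = D lap(c) - rho * Q_m * c / (K_m + c)` on the axisymmetric grid
#' with a cell-centred finite-volume scheme: harmonic-mean interface
#' diffusivities across the medium/gel discontinuity, a Dirichlet condition
#' `c = C_surface` on the free medium surface, and zero flux at the axis, dish
#' wall and dish base. The Michaelis-Menten nonlinearity is handled by Picard
#' iteration on the lagged denominator; each pass is a sparse symmetric
#' positive-definite solve, so the discrete maximum principle
#' `0 <= c <= C_surface` holds for every iterate.
#'
#' @param grid An [build_domain()] grid (or [slab_grid()] for 1-D checks).
#' @param params A [model_parameters()] object.
#' @param density_map A [cell_density_map()].
#' @param Q_m Maximum per-cell oxygen consumption rate (amol/cell/s).
#' @param tol_change Convergence tolerance on the maximum relative field
#'   change between Picard passes.
#' @param tol_flux Convergence tolerance on the relative flux imbalance
#'   (boundary influx vs integrated consumption).
#' @param max_iter Picard iteration cap.
#' @param init Optional initial concentration field (vector or matrix, uM)
#'   used to warm-start the iteration.
#' @param enforce_convergence If `TRUE` (default), a solve that fails to meet
#'   both tolerances within `max_iter` passes is an error carrying the solver
#'   diagnostics; set `FALSE` only to inspect unconverged iterates.
#'
#' @return An object of class `"concentration_field"`: the concentration
#'   matrix (`conc`, uM, `nr` x `nz`), the grid, parameters, density map and
#'   `Q_m`, and the diagnostics `iterations`, `max_change`, `flux_imbalance`,
#'   `converged`.
#' @examples
#' grid <- build_domain(construct_geometry(), resolution = 0.5)
#' field <- solve_steady(grid, model_parameters(), cell_density_map(20e6), 18.1)
#' central_o2(field)
#' @export
solve_steady <- function(grid, params, density_map, Q_m,
                         tol_change = 1e-8, tol_flux = 1e-6, max_iter = 500L,
                         init = NULL, enforce_convergence = TRUE) {
  stopifnot(inherits(grid, "axi_grid"), inherits(params, "model_parameters"),
            inherits(density_map, "cell_density_map"))
  if (!is.numeric(Q_m) || length(Q_m) != 1L || Q_m < 0)
    stop("Q_m must be a single non-negative rate (amol/cell/s)")
  ctx <- fv_context(grid, params, density_map)
  sol <- fv_solve(ctx, Q_m, init = if (is.null(init)) NULL else c(init),
                  tol_change = tol_change, tol_flux = tol_flux,
                  max_iter = max_iter)
  if (!sol$converged && enforce_convergence)
    stop(sprintf(paste0("steady solve did not converge in %d iterations ",
                        "(max relative change %.3g, flux imbalance %.3g)"),
                 sol$iterations, sol$max_change, sol$flux_imbalance))
  new_concentration_field(grid, params, density_map, Q_m, sol)
}

new_concentration_field <- function(grid, params, density_map, Q_m, sol) {
  structure(list(conc = matrix(sol$conc, grid$nr, grid$nz),
                 grid = grid, params = params, density_map = density_map,
                 Q_m = Q_m, iterations = sol$iterations,
                 max_change = sol$max_change,
                 flux_imbalance = sol$flux_imbalance,
                 converged = sol$converged),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(paste0("Steady oxygen field: Q_m = %.4g amol/cell/s, ",
                     "%d Picard iterations\n"), x$Q_m, x$iterations))
  cat(sprintf("  range %.4g - %.4g uM, flux imbalance %.2e%s\n",
              min(x$conc), max(x$conc), x$flux_imbalance,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Discrete flux balance of a solved field
#'
#' Relative imbalance between the diffusive influx through the Dirichlet
#' medium surface and the volume-integrated Michaelis-Menten consumption,
#' `|influx - consumption| / max(influx, consumption, eps)`. For a converged
#' solve this is below the solver's flux tolerance; a deliberately unconverged
#' field shows a large imbalance.
#'
#' @param field A [solve_steady()] result.
#' @return Dimensionless relative imbalance.
#' @export
flux_balance <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  ctx <- fv_context(field$grid, field$params, field$density_map)
  fv_imbalance(ctx, c(field$conc), field$Q_m)
}

#' Sample a concentration field at a point
#'
#' Bilinear interpolation between neighbouring cell centres; outside the
#' outermost cell centres the field is continued constantly, consistent with
#' the zero-flux boundaries at the axis and walls.
#'
#' @param field A [solve_steady()] result.
#' @param r,z Sample point (mm), inside the domain.
#' @return Named numeric vector `c(uM = ..., percent = ...)`.
#' @export
sample_at <- function(field, r, z) {
  stopifnot(inherits(field, "concentration_field"))
  r <- unname(r); z <- unname(z)
  g <- field$grid
  if (r < g$r_nodes[1L] || r > g$r_nodes[length(g$r_nodes)] ||
      z < g$z_nodes[1L] || z > g$z_nodes[length(g$z_nodes)])
    stop("sample point (", r, ", ", z, ") lies outside the domain")
  interp1 <- function(x, centers) {
    k <- findInterval(x, centers)
    if (k == 0L) return(list(lo = 1L, hi = 1L, w = 0))
    if (k >= length(centers)) return(list(lo = length(centers),
                                          hi = length(centers), w = 0))
    list(lo = k, hi = k + 1L,
         w = (x - centers[k]) / (centers[k + 1L] - centers[k]))
  }
  ir <- interp1(r, g$r_centers)
  iz <- interp1(z, g$z_centers)
  cmat <- field$conc
  v <- (1 - ir$w) * (1 - iz$w) * cmat[ir$lo, iz$lo] +
    ir$w * (1 - iz$w) * cmat[ir$hi, iz$lo] +
    (1 - ir$w) * iz$w * cmat[ir$lo, iz$hi] +
    ir$w * iz$w * cmat[ir$hi, iz$hi]
  c(uM = v, percent = conc_to_percent(v, field$params$uM_per_percent))
}

#' One-dimensional slab grid for solver verification
#'
#' Degenerate single-radial-cell configuration: a gel slab of given thickness
#' with the fixed-concentration surface on top and a no-flux base, uniformly
#' labelled `construct_core` so the whole slab consumes oxygen. Against this
#' configuration the solver can be compared with the classical closed-form
#' slab solutions (zero-order sink for `c >> K_m`, first-order sink for
#' `c << K_m`).
#'
#' @param thickness Slab thickness (mm).
#' @param dz Axial cell size (mm).
#' @param radius Radius of the single radial cell (mm); immaterial to the
#'   axial profile.
#' @return An `"axi_grid"` with `nr = 1`.
#' @export
slab_grid <- function(thickness, dz = 0.05, radius = 0.5) {
  nz <- max(2L, as.integer(ceiling(thickness / dz - 1e-9)))
  z_nodes <- seq(0, thickness, length.out = nz + 1L)
  r_nodes <- c(0, radius)
  rc <- radius / 2
  zc <- (utils::head(z_nodes, -1L) + utils::tail(z_nodes, -1L)) / 2
  dzv <- diff(z_nodes)
  structure(list(r_nodes = r_nodes, z_nodes = z_nodes,
                 r_centers = rc, z_centers = zc,
                 dr = radius, dz = dzv, nr = 1L, nz = nz,
                 region = matrix("construct_core", 1L, nz),
                 volume = outer(2 * pi * rc * radius, dzv),
                 geometry = NULL, resolution = dz),
            class = "axi_grid")
}
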