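#' Physical parameters of the oxygen diffusion-reaction model
#'
#' Bundles the physical constants of the steady diffusion-reaction model for
#' oxygen in an agarose construct: diffusivities in medium and gel, the gel
#' fluid volume fraction, the Michaelis constant, the oxygen concentration
#' prescribed at the medium surface, the conversion between percent oxygen and
#' micromolar concentration, and the initial (day-0) cell seeding density.
#'
#' Defaults correspond to a 2% agarose construct cultured under nominally 20%
#' oxygen: free-water oxygen diffusivity 3.0e-3 mm^2/s, fluid fraction 0.98
#' (giving a gel diffusivity of 2.77e-3 mm^2/s by the Mackie-Meares relation),
#' K_m = 63 uM, 185 uM at the medium surface, and a seeding density of
#' 20e6 cells/mL. The percent scale is calibrated so that 185 uM reads as 20%
#' oxygen (9.25 uM per percentage point).
#'
#' @param D_media Oxygen diffusivity in the culture medium (mm^2/s).
#' @param phi_f Fluid volume fraction of the gel, in (0, 1].
#' @param D_ag Oxygen diffusivity in the gel (mm^2/s). When `NULL` it is
#'   computed from `D_media` and `phi_f` with [mackie_meares()].
#' @param K_m Michaelis constant: oxygen concentration at which per-cell
#'   consumption runs at half its maximum (uM).
#' @param C_surface Oxygen concentration prescribed at the medium surface (uM).
#' @param uM_per_percent Conversion constant between % O2 and uM.
#' @param rho0 Initial cell seeding density (cells/mL).
#'
#' @return An object of class `"model_parameters"`.
#' @examples
#' p <- model_parameters()
#' p$D_ag          # 2.77e-3 mm^2/s
#' low_o2 <- model_parameters(C_surface = 50)
#' @export
model_parameters <- function(D_media = 3.0e-3,
                             phi_f = 0.98,
                             D_ag = NULL,
                             K_m = 63,
                             C_surface = 185,
                             uM_per_percent = 9.25,
                             rho0 = 20e6) {
  if (is.null(D_ag)) D_ag <- mackie_meares(D_media, phi_f)
  p <- list(D_media = D_media, D_ag = D_ag, phi_f = phi_f, K_m = K_m,
            C_surface = C_surface, uM_per_percent = uM_per_percent,
            rho0 = rho0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("model parameter '", nm, "' must be a single positive number")
  }
  if (p$phi_f > 1) stop("phi_f must lie in (0, 1]")
  if (p$D_ag > p$D_media)
    stop("gel diffusivity D_ag cannot exceed the free-medium value D_media")
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Oxygen diffusion-reaction model parameters\n")
  cat(sprintf("  D_media   %.3g mm^2/s\n", x$D_media))
  cat(sprintf("  D_ag      %.3g mm^2/s (phi_f = %.3g)\n", x$D_ag, x$phi_f))
  cat(sprintf("  K_m       %.4g uM\n", x$K_m))
  cat(sprintf("  C_surface %.4g uM (= %.3g%% O2 at %.4g uM/%%)\n",
              x$C_surface, x$C_surface / x$uM_per_percent, x$uM_per_percent))
  cat(sprintf("  rho0      %.3g cells/mL\n", x$rho0))
  invisible(x)
}

#' Mackie-Meares diffusivity correction for a polymer gel
#'
#' Reduces a solute's free-solution diffusivity to its value inside a gel as a
#' function of the gel's fluid volume fraction:
#' `D_gel = D_free * (phi_f / (2 - phi_f))^2`.
#'
#' @param D_free Free-solution diffusivity (mm^2/s), positive.
#' @param phi_f Fluid volume fraction of the gel, in (0, 1].
#' @return Diffusivity in the gel, same units as `D_free`.
#' @examples
#' mackie_meares(3.0e-3, 0.98)  # 2.77e-3 mm^2/s for 2% agarose
#' @export
mackie_meares <- function(D_free, phi_f) {
  if (!is.numeric(D_free) || any(D_free <= 0)) stop("D_free must be positive")
  if (!is.numeric(phi_f) || any(phi_f <= 0) || any(phi_f > 1))
    stop("phi_f must lie in (0, 1]")
  D_free * (phi_f / (2 - phi_f))^2
}

#' Michaelis-Menten per-cell oxygen consumption rate
#'
#' Actual consumption rate of a cell exposed to local oxygen concentration `c`:
#' `Q_m * c / (K_m + c)`. Saturates at `Q_m` for `c >> K_m` and is linear in
#' `c` for `c << K_m`.
#'
#' @param c Local oxygen concentration (uM), non-negative; vectorised.
#' @param Q_m Maximum per-cell consumption rate (amol/cell/s), non-negative.
#' @param K_m Michaelis constant (uM), positive.
#' @return Per-cell consumption rate in the units of `Q_m`.
#' @examples
#' mm_rate(63, 18.1, 63)  # half-saturation: Q_m / 2
#' @export
mm_rate <- function(c, Q_m, K_m) {
  if (any(c < 0)) stop("oxygen concentration c must be non-negative")
  if (any(Q_m < 0)) stop("Q_m must be non-negative")
  if (any(K_m <= 0)) stop("K_m must be positive")
  Q_m * c / (K_m + c)
}

#' Convert between percent oxygen and micromolar concentration
#'
#' Linear two-point-calibrated conversion between the sensor's percent-oxygen
#' scale and molar concentration; 0% maps to 0 uM. The default constant,
#' 9.25 uM per %, makes 185 uM read as exactly 20% O2.
#'
#' @param pct Oxygen level (% O2), non-negative; vectorised.
#' @param conc Oxygen concentration (uM); vectorised.
#' @param uM_per_percent Conversion constant (uM per % O2), positive.
#' @return `percent_to_conc` returns uM; `conc_to_percent` returns % O2.
#' @examples
#' percent_to_conc(20)      # 185 uM
#' conc_to_percent(50)      # 5.405 %
#' @export
percent_to_conc <- function(pct, uM_per_percent = 9.25) {
  if (any(pct < 0)) stop("percent oxygen must be non-negative")
  if (uM_per_percent <= 0) stop("uM_per_percent must be positive")
  pct * uM_per_percent
}

#' @rdname percent_to_conc
#' @export
conc_to_percent <- function(conc, uM_per_percent = 9.25) {
  if (uM_per_percent <= 0) stop("uM_per_percent must be positive")
  conc / uM_per_percent
}

#' Volumetric oxygen sink from per-cell rate and cell density
#'
#' Converts a per-cell maximum consumption rate (amol/cell/s) and a cell
#' density (cells/mL) into the volumetric sink density rho*Q_m that enters the
#' governing equation, in mol/(mm^3 s):
#' `Q_m * 1e-18 * rho * 1e-3`.
#'
#' @param Q_m Per-cell consumption rate (amol/cell/s), non-negative.
#' @param rho Cell density (cells/mL), non-negative.
#' @return Volumetric consumption rate in mol/(mm^3 s).
#' @examples
#' volumetric_sink(18.1, 20e6)  # 3.62e-13 mol/(mm^3 s)
#' @export
volumetric_sink <- function(Q_m, rho) {
  if (any(Q_m < 0) || any(rho < 0))
    stop("Q_m and rho must be non-negative")
  (Q_m * 1e-18) * (rho * 1e-3)
}

#' Exact unit conversions for the quantities handled by the model
#'
#' Small unit-safety helper covering the conversions the pipeline needs:
#' `uM` <-> `%O2` (via the calibration constant), `cells/mL` <-> `cells/mm3`,
#' `amol` <-> `mol`, and identity for `mm2/s`. All conversions are exact
#' ratios, so round trips are identities to machine precision.
#'
#' @param x Numeric value(s) to convert.
#' @param from,to Unit strings; one of `"uM"`, `"%O2"`, `"cells/mL"`,
#'   `"cells/mm3"`, `"amol"`, `"mol"`, `"mm2/s"`.
#' @param uM_per_percent Calibration constant used for `uM` <-> `%O2`.
#' @return Converted numeric value(s).
#' @examples
#' convert_units(185, "uM", "%O2")        # 20
#' convert_units(20e6, "cells/mL", "cells/mm3")  # 2e4
#' @export
convert_units <- function(x, from, to, uM_per_percent = 9.25) {
  units <- c("uM", "%O2", "cells/mL", "cells/mm3", "amol", "mol", "mm2/s")
  if (!from %in% units || !to %in% units)
    stop("unknown unit; supported: ", paste(units, collapse = ", "))
  if (from == to) return(x)
  key <- paste(from, to, sep = "->")
  switch(key,
    "uM->%O2" = x / uM_per_percent,
    "%O2->uM" = x * uM_per_percent,
    "cells/mL->cells/mm3" = x * 1e-3,
    "cells/mm3->cells/mL" = x * 1e3,
    "amol->mol" = x * 1e-18,
    "mol->amol" = x * 1e18,
    stop("no conversion from '", from, "' to '", to, "'")
  )
}
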