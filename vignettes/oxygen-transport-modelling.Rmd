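---
title: "Modelling oxygen transport and consumption in cell-seeded agarose constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxygen transport and consumption in cell-seeded agarose constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxygel)
```

## The model

A cylindrical cell-seeded agarose construct (Ø5 × 3 mm by default) sits in
a 1.5 mm deep recess of a 3 mm acellular agarose bed at the centre of a
60 mm dish, with culture medium filling the dish to 1 mm above the
construct top. Oxygen dissolves at the medium's free surface, diffuses down
through the medium and the gel, and is consumed by the encapsulated cells.
After the initial equilibration the field is quasi-steady, so we solve

$$0 = D\,\nabla^2 c \;-\; \rho\,\frac{Q_m\,c}{K_m + c}$$

on the axisymmetric $(r,z)$ domain, where $c$ is oxygen concentration
(µM), $D$ the diffusivity ($D_{media}$ in the medium, $D_{ag}$ in bed and
construct), $\rho$ the local cell density (zero outside the construct),
$Q_m$ the maximum per-cell consumption rate and $K_m$ the oxygen level at
half-maximal consumption. The free medium surface is a Dirichlet boundary
at $C_{surface}$; the dish wall, dish base and symmetry axis are zero-flux.
There is no lateral free surface: the medium is bounded by the dish wall.

Assumptions worth stating explicitly: no convection in the medium (the
dish is static), no consumption by the medium or the acellular bed, the
sensor probe does not perturb the field, the construct sits in perfect
contact with the bed (no fluid gap), and the twice-weekly media exchanges
are not modelled — the solve represents the equilibrated state between
them.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `D_media` | 3.0×10⁻³ | mm²/s | oxygen diffusivity in medium (free water) |
| `phi_f` | 0.98 | — | fluid volume fraction of 2% agarose |
| `D_ag` | 2.77×10⁻³ | mm²/s | gel diffusivity, from the Mackie–Meares relation |
| `K_m` | 63 | µM | Michaelis constant |
| `C_surface` | 185 (or 50) | µM | oxygen at the medium surface, 20% (or 5%) incubator |
| `uM_per_percent` | 9.25 | µM/% | sensor-scale calibration |
| `rho0` | 20×10⁶ | cells/mL | seeding density (40×10⁶ in the high-density arm) |

Two of these deserve comment, because the source material for this class
of experiment is often ambiguous about them:

* **`K_m` units.** Michaelis constants for chondrocyte-like oxygen
  consumption are tabulated in many unit systems, and a misread of
  µmol/mm³ for µM changes the constant by nine orders of magnitude. The
  governing equation requires `K_m` commensurate with `c`, and 63 µM is
  the only physically admissible reading of the printed digits, so that is
  the default; it is configurable per scenario (`model_parameters(K_m = )`).
* **Percent scale.** Fiber-optic sensors report "% oxygen" after a
  two-point calibration. We adopt a linear scale with 0% ↔ 0 µM and
  calibrate the slope on the high-oxygen pair (185 µM ↔ 20%), giving
  9.25 µM per point. The low-oxygen condition (50 µM nominal 5%) then
  reads 5.405%; that internal inconsistency of the inputs is accepted
  rather than hidden, and the constant is configurable.

The Mackie–Meares relation itself is implemented in the squared-ratio form
$D_{gel} = D_{free}\,(\phi_f/(2-\phi_f))^2$, the standard form of that
correction, which reproduces the tabulated 2.77×10⁻³ mm²/s from the
free-water value at $\phi_f = 0.98$.

## Discretisation and numerics

The geometry is a union of axis-aligned rectangles in $(r,z)$, so we use a
structured cell-centred finite-volume grid rather than unstructured finite
elements: flux conservation and the discrete maximum principle then hold
by construction. Grid spacing is adjusted per segment so that every
material interface lands exactly on a grid line; cell volumes are the
exact revolved volumes $2\pi \bar r\,\Delta r\,\Delta z$. The default
spacing is 0.1 mm (16,500 cells for the default dish), with refinement
supported; the central prediction changes by less than 0.5% between 0.1
and 0.05 mm spacing on the baseline scenario, which the test suite checks.

Interface diffusivities are harmonic means weighted by the half-cell
distances, making the flux across the medium/gel discontinuity exactly
continuous. The Michaelis–Menten nonlinearity is handled by Picard
iteration on the lagged denominator: each pass solves a symmetric
positive-definite M-matrix system (sparse Cholesky, with the symbolic
factorisation reused across passes), so every iterate satisfies
$0 \le c \le C_{surface}$. The sink is evaluated with $c$ clamped at zero
so an intermediate undershoot can never act as a source. Convergence
requires both a maximum relative field change below 10⁻⁸ and a relative
flux imbalance (surface influx vs integrated consumption) below 10⁻⁶,
within a cap of 500 iterations; a solve that fails to converge is an
error carrying the diagnostics, never a silently returned field.

Point sampling is bilinear between cell centres, continued constantly
beyond the outermost centres (consistent with the zero-flux boundaries).
Grid cells are half-open, lower-inclusive intervals, so a point on an
interior grid line belongs to the cell whose lower edge it is — a fixed,
documented tie-break.

## Inverse estimation of the consumption rate

The central oxygen prediction is strictly decreasing in $Q_m$ (verified
numerically as a property test), so matching a sensor reading is a
bracketed scalar root-finding problem. `fit_qm()` uses regula falsi with
Illinois damping inside a maintained bracket (default [0, 200]
amol/cell/s, doubled up to six times if needed), warm-starting each
forward solve from the previous field, and stops when predicted and
observed central oxygen agree to 0.01 percentage points. Readings above
the zero-consumption prediction are reported as infeasible; the residual
and bracket are always part of the estimate object.

A reading of 0.0% cannot be matched exactly — the Michaelis–Menten sink
vanishes with $c$, so the model approaches zero only asymptotically.
`min_qm_for_depletion()` instead returns the smallest $Q_m$ whose
predicted centre falls to a threshold $\varepsilon$, flagged
`is_lower_bound` with $\varepsilon$ recorded. The default
$\varepsilon = 0.05\%$ is half the last printed digit of the sensor
readout. These lower bounds are markedly sensitive to both $\varepsilon$
and $K_m$: with $K_m = 63$ µM the near-zero sink is weak, so depleting the
final fraction of a percentage point requires a disproportionately large
$Q_m$. Consequently a rate fitted from a *non-zero* reading is far more
robust than a lower bound inferred from a depleted one, and forward
predictions run at a consumption rate that was itself derived as a
depletion lower bound under different kinetics can disagree with the
measured 0.0% by several tenths of a percentage point. The package
reports such forward predictions as computed (e.g. 0.8% at
43.2 amol/cell/s under the defaults) rather than forcing them to zero;
users comparing against depleted sensor readings should treat the
$K_m$–$\varepsilon$ pairing as the dominant source of uncertainty.

Batch fitting (`fit_qm_batch()`) inverts each replicate separately and
reports per-condition mean ± SD, matching the replicate structure of the
experiments (n = 3 per condition); it never fits a joint model across
replicates.

## Biochemistry to cell densities

Day-24 cell densities come from DNA assays: each region's day-24 DNA is
normalised to the mean day-0 DNA and the ratio multiplied by the seeding
density. Region-matched day-0 means are used when available; otherwise the
whole-construct day-0 mean is scaled by the region's volume fraction
(inner Ø3 mm biopsy-punch core vs surrounding annulus, over the full
height). Wet-weight percentages are plain mass percent with the wet weight
converted from mg to µg. Group hypothesis testing is out of scope; the
package stops at per-sample metrics and group mean ± SD.

## The synthetic-data generator

The generator exists so the full pipeline is exercisable end-to-end
without experimental data. It emulates:

* **Sensor readings** — the forward model's central prediction at an
  arm's true $Q_m$, plus additive Gaussian noise (SD 0.3 percentage
  points, the magnitude of the reported replicate spread) clipped at zero,
  the physical floor of the readout.
* **Assay tables** — DNA from the seeded cell number (7.7 pg/cell) scaled
  by each arm's DNA growth ratio (1.4 for the stem-cell sources, 0.8 for
  chondrocytes), with multiplicative lognormal noise (CV 10%, keeping
  masses positive); sGAG and collagen as logistic responses to the
  region's mean oxygen — deposition rising as oxygen falls, with collagen
  additionally suppressed below a 2% knee. The response curves are test
  fixtures calibrated to reproduce the qualitative spatial structure, not
  mechanistic claims.

The ten presets cover five arms (BMSC/FPSC/CC at 20% oxygen and 20e6
cells/mL, BMSC at 5% oxygen, BMSC at 40e6 cells/mL) at day 0 and day 24,
parameterised by each arm's reported consumption rates. The day-0 rates of
the low-oxygen and high-density arms are not separately tabulated, so those
presets reuse the BMSC day-0 value (43.2 amol/cell/s) — the same cell
population — as the generator truth.

What the generator does **not** emulate: within-region density gradients,
dead-cell DNA retained in the gel (which inflates apparent densities),
temporal drift of $K_m$ or $Q_m$ between measurement days, matrix-dependent
diffusivity changes, and glucose co-limitation. Passing recovery tests on
synthetic data therefore demonstrates the estimator's correctness under
the model's own assumptions, not the validity of those assumptions for
real constructs.

## Problem sizes and test design

The test-suite defaults balance fidelity against runtime: most behavioural
tests run at 0.25–0.5 mm spacing (a few hundred to a few thousand cells),
where every qualitative property of the solution is already resolved;
quantitative reproduction checks run at the production spacing of 0.1 mm;
the mesh-convergence check compares 0.1 against 0.05 mm; and the
1-D closed-form comparisons (zero-order and first-order slab limits) use
0.05 mm cells. The noisy-recovery study uses 50 synthetic replicates at
0.2 mm spacing. Randomised property sweeps (maximum principle) use a
reduced-dish geometry with identical topology.

## Known limitations

* Steady state only: no transient integrator, so the approach to
  equilibrium after a media exchange is out of reach.
* The depletion lower bound depends on the $\varepsilon$ convention and on
  $K_m$, as discussed above; with the default $K_m$ the model does not
  reproduce full central depletion at consumption rates that depletion
  lower bounds of this magnitude would suggest.
* The percent calibration cannot satisfy both tabulated
  concentration/percent pairs simultaneously; the high-oxygen pair is
  authoritative by default.
* Media geometry is idealised (flat free surface, fixed depth, no
  meniscus or evaporation).
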