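---
title: "Water-bolus thermal dosimetry: models, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-bolus thermal dosimetry: models, assumptions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bolusplan)
```

## The problem

In microwave hyperthermia of the head-and-neck region, a phased-array
applicator deposits electromagnetic power (SAR, W kg⁻¹) in tissue while a
water bolus — a water-filled bag circulating temperature-controlled,
demineralized water between applicator and skin — couples the energy into the
patient and cools the skin. Two bolus parameters shape the superficial
temperature field: the circulating-water temperature $T_{wb}$ and the
convective heat-transfer coefficient $h$ (W m⁻² K⁻¹) of the bolus–skin
interface. `bolusplan` provides the computational chain needed to study their
influence on treatment quality: a voxel bioheat solver, an estimator for $h$
from bench measurements, power tuning against a healthy-tissue temperature
cap, and the $T_{wb} \times h$ sweep that summarizes target coverage (T50)
and required power (mean target SAR) as a function of target depth.

## The bioheat model

Temperatures obey the Pennes bioheat equation on a labeled voxel grid:

$$ c\rho\,\frac{\partial T}{\partial t} \;=\; \nabla\!\cdot\!(k \nabla T)
   \;-\; SF\,\rho_b c_b\, \rho\, \omega\,(T - T_b) \;+\; \rho\,\mathrm{SAR}
   \;+\; \rho\,Q $$

with $c$ the specific heat (J kg⁻¹ K⁻¹), $\rho$ density (kg m⁻³), $k$ thermal
conductivity (W m⁻¹ K⁻¹), $\omega$ blood perfusion (ml min⁻¹ kg⁻¹, converted
internally by $10^{-6}/60$ to m³ s⁻¹ kg⁻¹), $T_b$ arterial blood temperature
(default 37 °C, configurable — the package does not assume a printed value),
$Q$ metabolic heat (W kg⁻¹) and $SF$ a dimensionless, temperature-dependent
perfusion scaling factor. Blood carries $\rho_b = 1050$ kg m⁻³ and
$c_b = 3617$ J kg⁻¹ K⁻¹.

Tissue constants live in a CSV table (`default_tissue_table()`) with a
parallel starred column set. Two perfusion models are supported:

* **Constant thermal stress** (`perfusion_model("constant_stress")`):
  $SF \equiv 1$ with the starred $k/\omega$ values for fat, muscle and tumor —
  elevated "under heating" constants fitted from clinical temperature data.
* **Temperature dependent** (`perfusion_model("temperature_dependent")`):
  baseline (37 °C) constants with $SF$ rising piecewise-linearly to 2 (fat)
  and 8.9 (muscle) between 37 and 44 °C, constant outside the breakpoints.
  The tumor curve defaults to flat $SF = 1$: its 1.85× elevation over muscle
  is already contained in the baseline $\omega = 72.3$ ml min⁻¹ kg⁻¹, and we
  deliberately do not invent an unpublished tumor trajectory — users can
  supply their own breakpoints. Above the last breakpoint $SF$ is held at its
  44 °C value; healthy tissue is capped at 44 °C anyway, so the choice only
  affects tumor voxels slightly above the cap.

Thermal conductivity is *not* temperature-scaled in either model; only
perfusion is.

## Discretization and boundary conditions

The solver uses a 7-point finite-volume stencil on the uniform voxel grid
(cell-centered unknowns). Face conductances take the harmonic mean of the two
adjacent conductivities, which is exact for layered media. Three boundary
classes exist:

* **bolus** — exterior faces of bolus-contact voxels: Robin condition with
  film coefficient $h$ in series with the half-cell conduction resistance,
  $U = \left(\frac{\Delta x}{2k} + \frac{1}{h}\right)^{-1}$. As
  $h \to \infty$ this tends to the Dirichlet limit $2k/\Delta x$; $h = 0$ is
  adiabatic. The water bolus is modeled as this single surface condition
  rather than a meshed flowing-water object — a mean film coefficient on the
  contact surface is sufficient for whole-target dosimetry, which is also why
  a single measured mean $h$ is a useful system property.
* **exterior** — remaining exterior faces: adiabatic by default in treatment
  simulations (the patient is enclosed by the applicator), Robin to room air
  (default $h_{air} = 10$ W m⁻² K⁻¹) in the bench experiment.
* **inactive** — interfaces with thermally inactive labeled tissue (lung,
  internal air): Dirichlet, default 37 °C, configurable.

**Linear algebra.** The discrete operator is symmetric positive definite.
Systems up to 4000 unknowns are solved directly (sparse Cholesky/LU); larger
systems use Jacobi-preconditioned conjugate gradients with a relative
residual of 10⁻¹⁰ and warm starts from the previous iterate, which makes
repeated solves (fixed-point iterations, transient steps, power bisection)
cheap. The solver contract is solver-agnostic: residuals far below the 10⁻⁸
contract in either path.

**Nonlinearity.** The temperature-dependent model re-evaluates $SF$ at the
current iterate and re-solves, with damping factor 0.5 and tolerance
$10^{-3}$ °C on the maximum update. Damping is needed for robustness against
the steep 8.9× muscle ramp. With flat $SF \equiv 1$ breakpoints the iteration
reproduces the constant-model solution to solver tolerance.

**Transient stepping** uses backward Euler by default (unconditionally
stable; the operator is factor- or preconditioner-reused when it is
temperature-independent) and optionally explicit Euler, which refuses time
steps above its stability bound $\min_i(M_{ii}/A_{ii})$ with an error stating
the bound.

## The bench experiment and $h$ estimation

The heat-transfer coefficient is estimated as in the classic bench procedure:
a muscle-equivalent gel slab equilibrated at room temperature (19.6 °C) is
put in contact with the bolus circulating at 31.1 °C, and fiber-optic probes
record transient temperatures while heat soaks in. The synthetic bench
(`experiment_config()`) uses a 48 × 80 × 80 mm slab at 2 mm spacing, 21
measurement points (7 depths × 3 lateral offsets — the bench geometry is not
published, so the layout is parameterized), a 1200 s record sampled every
60 s and a 30 s implicit step. The gel carries muscle $k$ and $c$ with
$\omega = Q = 0$ (muscle-equivalent by recipe, unperfused by construction).

`fit_h()` minimizes $SSR(h) = \sum_t (T_{sim}(h,t) - T_{meas}(t))^2$ over
$h \in [10, 1000]$ W m⁻² K⁻¹ by golden-section/parabolic search
(`stats::optimize`), returning $R^2$ and flagging fits that terminate at a
bound instead of silently returning them. Because the transient solve does
not depend on the probe, candidate-$h$ simulations are cached per experiment
configuration and shared across the 21 per-probe fits. Each probe is fitted
independently (one coefficient per measurement point, then averaged); a
pooled fit over summed SSR is possible by concatenating records but is not
the default.

Recovery is validated on self-generated records: noiseless records return
their generating coefficient to well under 1%, and with 0.05 °C Gaussian
measurement noise the 21-probe mean stays within a few per mille of the truth.
Note what this does and does not show: the synthetic bench shares the solver
with the fitter (a deliberate inverse-crime design that isolates the
estimator), so it validates the optimization machinery, not the physical
fidelity of any real bolus.

## Dose metrics and power tuning

* **T50** — the temperature exceeded by half of the target voxels —
  is computed as the lower-interpolation 50th percentile (sorted ascending,
  element $\lceil n/2 \rceil$; for even counts the lower middle value). An
  exhaustive counting oracle over small sets pins the convention down in the
  tests.
* **Mean target SAR** is the arithmetic CTV mean of `power_scale * sar`.
* **CTV depth** is the per-voxel Euclidean distance to the nearest
  bolus-contact voxel center; the median depth (depth of half the target
  volume) stratifies targets as shallow (< 20 mm) or deep (≥ 20 mm; the
  boundary goes to the deep group because the shallow class is strictly
  below the threshold).
* **Power tuning** (`tune_power()`) scales the SAR field so the *maximum*
  steady temperature over healthy tissue — all thermally active voxels
  outside the CTV; bolus and inactive voxels excluded — equals 44 °C within
  0.01 °C. The voxel maximum (not a percentile) is used as the cap. For the
  constant model the temperature rise is linear in power, so two solves give
  the exact scale as the smallest scale at which any healthy voxel reaches
  the cap (the limiting voxel is found, not assumed). The temperature-
  dependent model bisects on the power scale, exploiting monotonicity of the
  healthy maximum in power and warm-starting each nonlinear solve.

## The synthetic study and what it emulates

Patient CT models and clinically optimized SAR fields are private, so the
sweep operates on synthetic cases built by the package's own generators:

* `make_layered_phantom()` / `make_cylinder_phantom()` — fat-over-muscle
  slabs (the property table has no skin entry, so default layering starts at
  fat) and concentric-cylinder neck stand-ins, 2 mm default spacing (a
  desk-scale compromise; the spacing is a knob).
* `place_ctv()` — spherical tumor targets at controlled median depth. The
  shallow fixture (center 8 mm, radius 8 mm; median ≈ 8 mm, minimum ≈ 2 mm)
  reaches the immediate subsurface, as every shallow-median target in the
  study population does; the deep fixture sits at 40 mm median depth.
* `place_rod()` — critical-structure stand-ins: a spinal-cord rod at 26 mm
  depth and a superficial eye-like sclera rod at 6 mm, so the critical-tissue
  set contains both a deep and a superficial structure.
* `make_focal_sar()` — a Gaussian focus (here fwhm 15 mm) plus a laterally
  localized, exponentially decaying superficial component, scaled per tissue
  by $\sigma/\rho$ relative to the focus tissue: at a given field strength,
  absorbed power per unit mass is proportional to electrical conductivity
  over density, so fat and bone absorb an order of magnitude less than
  muscle or tumor. A uniform whole-surface skin load would not be a
  plausible stand-in for a phase/amplitude-optimized pattern.

These fixtures reproduce the study's qualitative conclusions at the measured
mean coefficient $h = 292$ W m⁻² K⁻¹: shallow-target T50 is non-decreasing in
$T_{wb}$ over 20–35 °C in both perfusion models and its summed 20→40 °C
gradient is positive, the deep constant-stress gradient is negative, the
allowed mean SAR at the cap shrinks as the bolus warms, T50 responds more
strongly to $T_{wb}$ than to $h$, and mean critical-tissue maxima rise with
$T_{wb}$. They are *not* patient anatomies: single spherical targets in
layered slabs, analytic SAR stand-ins, no air cavities, no inter-patient
averaging. Passing trends show the pipeline produces the right physics on
controlled geometry, not that any specific patient's numbers are reproduced.

## Numerical choices and degenerate inputs

* Sweep defaults: $T_{wb}$ from 20 to 42.5 °C in 2.5 °C steps (10 values) ×
  9 film coefficients linearly spaced over the measured 59–520 W m⁻² K⁻¹
  range (the measured spacing is unpublished; the list is overridable) = 90
  combinations per case and model. The acceptance checks run a reduced
  4 × 3 grid on two fixture cases (~32 k unknowns each) to stay desk-scale.
* `delta_t50_gradient()` sums consecutive T50 steps from 20 to 40 °C and
  asserts the telescoping identity (the sum equals T50(40) − T50(20)); any
  increasing series with those endpoints is accepted.
* Degenerate inputs error early and specifically: empty property tables,
  negative constants (named row/column), zero-radius targets, spheres
  escaping active tissue, identically zero SAR under power tuning, baseline
  temperatures already above the cap, probes outside the grid, minimizers at
  a fitting bound (flagged, excluded from summaries with a warning).
* Solver failures inside a sweep are recorded per grid point and the sweep
  continues; only a fully failed sweep raises.

## Known limitations

* No discrete-vasculature modeling and no bolus-flow CFD: the bolus is a
  single Robin surface with one mean $h$.
* The SAR generator is an analytic stand-in; it carries no antenna model,
  no standing-wave structure and no segmentation noise.
* Perfusion nonlinearity is a fixed-point (not Newton) iteration; extremely
  steep user-supplied SF curves may need smaller damping.
* The 44 °C cap is enforced on the healthy voxel maximum; a single hot voxel
  therefore controls total power, which is conservative on coarse grids.
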