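---
title: "From aneurysm hemodynamics to chip perfusion: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From aneurysm hemodynamics to chip perfusion: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

aneuflow links two well-separated flow problems. Upstream, blood flow through
an intracranial-aneurysm geometry determines where the endothelium
experiences abnormally low or high wall shear stress (WSS) — the mechanical
signal implicated in aneurysm formation, growth and rupture. Downstream, a
microfluidic culture channel must expose endothelial cells to exactly those
stress levels. The package implements the computational chain between them:
geometry, an immersed-boundary Navier–Stokes solver, WSS extraction, shear
sites, and the algebra that converts a target stress into a pump flow rate.

## Flow model and its assumptions

The solver integrates the incompressible Navier–Stokes equations for a
Newtonian fluid,

$$\partial_t u + \nabla\!\cdot\!(u\,u) = -\nabla p + \tfrac{1}{Re}\nabla^2 u
  - \tfrac{\chi}{\eta}\,u, \qquad \nabla\!\cdot\!u = 0,$$

nondimensionalized by the supplying-vessel diameter $D$ (4 mm by default),
the mean inlet speed $U$ (0.2 m/s) and the kinematic viscosity of blood
($3.25\times10^{-6}\,$m$^2$/s), giving $Re = UD/\nu \approx 246$ — the value
conventionally rounded to 250 for proximal cerebral vessels. The last
momentum term is the Brinkman volume penalization: $\chi$ is a binary
indicator equal to 1 inside solid (vessel wall) cells of a uniform Cartesian
grid, and $\eta \ll 1$ forces the velocity in those cells toward zero. This
is what lets a voxelized segmentation (or a synthetic mask) be simulated
without any body-fitted meshing.

Assumptions worth keeping in mind: Newtonian rheology (reasonable in vessels
of this caliber), rigid walls, a single steady or single-harmonic pulsatile
inlet, and — in the package's default configuration — a two-dimensional
section of the vessel–sac system. Patient-resolution three-dimensional runs
at 30–40 cells/mm over centimeters of vasculature are cluster-scale; the
desk-scale package exercises the identical discretization on 2-D sections
(first-class) and coarse 3-D grids (supported), which is sufficient for
every property the tests assert but does not reproduce patient-specific
stress magnitudes. Secondary (out-of-plane) flow in the sac, vessel
tortuosity and wall compliance are therefore absent by construction.

## Discretization

Variables live on a staggered (MAC) arrangement — face-normal velocities,
cell-centered pressure — which avoids pressure checkerboard modes without
stabilization. One step of `advance_flow()` is a fractional step:

1. **Explicit advection + diffusion.** Conservative second-order central
   fluxes; variable-step Adams–Bashforth 2 in time (Euler on the first
   step). The time step obeys both the advective CFL bound and the explicit
   viscous bound $\Delta t \le \mathrm{cfl}\cdot Re\,h^2/(2d)$.
2. **Implicit penalization.** $u \leftarrow u/(1 + \Delta t\,\chi_f/\eta)$ on
   faces adjacent to solid cells. The stiffness of $\eta = 10^{-8}$ forbids
   explicit treatment; the exact integrating factor costs one division.
3. **Projection.** A pressure Poisson solve restores a discretely
   divergence-free field in every fluid cell, to machine precision with the
   cached sparse Cholesky factorization used here.

Two design points deserve explanation because they deviate from what a
first-pass implementation usually does:

**Penalization-weighted projection.** With a uniform-coefficient Laplacian,
the projection re-injects a velocity $\sim \Delta t\,\nabla p$ through wall
faces after the penalization has zeroed them — an $\eta$-independent leak
that caps how solid the "solid" ever gets. aneuflow's Poisson operator is
the symmetric 5/7-point Laplacian with face transmissibilities $\beta = 1$
between fluid cells and $\beta = \eta/(\eta + \Delta t_{\mathrm{ref}})$ on
solid-adjacent faces — the same screening factor the implicit penalization
applies — and the velocity correction uses the identical weights. Fluid-cell
divergence remains exact (every face of a fluid cell carries its matrix
weight), while the measured maximum solid-cell speed decays like
$O(\eta)$, comfortably below the classical $O(\sqrt{\eta})$ penalization
error bound. The weights use a fixed reference $\Delta t$; because matrix
and correction share them, the projection stays exact for any actual step
size. The test suite verifies monotone decay across
$\eta \in \{10^{-4}, 10^{-6}, 10^{-8}\}$ and the $\sqrt{\eta}$ envelope.

**Walls live on cell centers.** With $\eta$ far below the grid scale the
Brinkman screening length $\sqrt{\nu\eta}$ is sub-cell, so the discrete
no-slip surface sits at the centers of the first solid cells — not at the
fluid/solid face. Two consequences follow. The mask generators snap planar
walls to the cell-center lattice, so the effective channel width equals the
requested diameter exactly (a face-aligned wall would be effectively half a
cell too wide on each side, a 3% centerline-velocity bias at 32 cells
across). And the WSS gradient treats the first fluid sample as sitting one
full cell, not half a cell, from the wall. The one-sided two-point stencil

$$\left.\frac{\partial u_t}{\partial n}\right|_{w}
  \approx \frac{4u_1 - u_2}{2h}$$

(samples at $h$ and $2h$ along the inward normal) is exact for linear and
parabolic profiles over that geometry and falls back to first order
($u_1/h$) at corners without a second fluid sample. Staircase jitter on
oblique walls remains the dominant WSS error; site statistics therefore use
medians.

Other numerical choices: the pure-Neumann pressure nullspace is removed by
pinning one cell (the right-hand side is mean-corrected first); the outlet
copies the last interior plane (zero gradient) and is then rescaled so the
outflow flux equals the inflow flux exactly, which is why global mass
balance holds to rounding; the inlet ramps up smoothly over 0.5 convective
time units to soften the impulsive start (the ramp is over long before any
reported statistic); the solver contains no randomness anywhere — identical
configurations give bitwise-identical fields. Degenerate inputs error
eagerly: masks whose fluid phase is not a single inlet-connected component,
non-watertight STL surfaces (reported with their open-edge count),
sub-resolution vessels (fewer than 8 cells across), NaN blow-ups (reported
with step and $\Delta t$).

## Synthetic geometry: what it emulates, and what it does not

The generators produce the study's geometry family: a straight supplying
vessel of diameter 4 mm, optionally carrying a circular/spherical sidewall
sac (default radius 2 mm, neck 1.6 mm) whose center sits
$b = \sqrt{r^2 - (w_n/2)^2}$ beyond the wall so the neck chord has exactly
the requested width. These defaults are a plausible small sidewall aneurysm;
they are not matched to any patient (sac dimensions are typically not
reported alongside such studies). `voxelize_stl()` accepts a watertight
surface export instead, rasterized by even–odd parity counting along a fixed
axis with a deterministic sub-cell ray offset for tie-breaking, and
`refine_mask()`/`smooth_mask()` reproduce the resolution-translation and
light surface-smoothing steps of an imaging pipeline (2 px/mm imagery
refined 16× lands at 32 cells/mm, inside the 30–40 cells/mm band of highly
resolved runs).

Passing tests on this family show that the discretization, the WSS
extraction and the site logic behave correctly — they do not show that a
2-D circular sac predicts any patient's stress magnitudes. What does carry
over from the study geometry is the robust qualitative topology, which the
refined acceptance run reproduces: the highest wall stress concentrates at
the downstream sac–vessel rim, the lowest on the sac wall away from the
neck.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `reynolds` | derived (≈246) | – | $UD/\nu$ of the vessel |
| `penalization_eta` | 1e-8 | – | Brinkman parameter; smaller = harder wall |
| `cfl` | 0.5 | – | fraction of the stability-limited step |
| `steady_tol` | 1e-6 | – | $\max|\Delta u|/\Delta t / U$ declaring steadiness |
| `poisson_tol` | 1e-10 | – | fluid-divergence contract is 10× this |
| waveform `amplitude`, `period` | 0.3, 1 (when pulsatile) | –, $D/U$ | $U(t) = U(1+\alpha\sin 2\pi t/T)$ |
| `low/high_percentile` | 5 / 95 | % | site thresholds on the WSS distribution |
| `min_region_faces` | 3 | faces | suppress single-voxel site fragments |
| chip `h, w, L` | 0.1, 1.2, 56 | mm | culture-channel cross-section |
| chip `viscosity` | 7e-4 | Pa s | water at 37 °C (medium surrogate) |

The sinusoidal waveform is the minimal "heartbeat" surrogate — measured
cardiac waveforms are multi-harmonic and asymmetric, and no waveform shape
is standard for this vessel; anyone with a patient waveform can replace the
single harmonic by driving `advance_flow()` directly. The percentile
thresholds (5/95) select the tails that published flow maps mark with single
low/high markers; no threshold convention is standard either, so both the
time-averaged and the peak field are available for pulsatile runs (the
time-averaged field feeds site extraction by default). Because published
condition values do not state whether they are sac-averaged, pointwise,
time-averaged or peak, the WSS module reports median and mean per site, in
nondimensional and Pa forms, so any convention can be matched downstream.

The CFD stage uses blood ($\nu = 3.25\times10^{-6}$ m²/s, $\rho$ defaulting
to 1060 kg/m³ — the density is a documented default, not a measured input),
while the chip stage deliberately uses the culture medium's water-like
viscosity; the two stages model different fluids on purpose, and both appear
as separate config keys.

## The chip map and its published inconsistency

The parallel-plate formulas $\gamma = 6Q/(h^2 w)$ and $\tau = \gamma\mu$ are
implemented verbatim as the primary mapping, with the exact inverse
$Q = \tau h^2 w/(6\mu)$. A rectangular-duct series correction would be more
accurate at $h/w = 1/12$ (the error bound is ~10%), but the printed
approximation is kept as the default so outputs match the formulas users
will find next to their hardware; the solver cross-check (a steady run
through the chip cross-section) confirms the mapping within that bound.
`check_operating_pair()` exists because published operating pairs are not
always self-consistent: a known example states 0.03 Pa at
$8.67\times10^{-10}$ m³/s in this very channel, where the formula yields
0.30 Pa — exactly 10× off, with a companion table printing "2 Pa" where the
text says 1.5 Pa. Which number carries the typo is undecidable from the
source, so the package surfaces the disagreement as a warning and never
silently corrects either value; only the self-consistent
(1.5 Pa, $4.33\times10^{-9}$ m³/s) pair is used as a reference point.

## Verification strategy and problem sizes

The test suite favors exact and analytic oracles: plane Poiseuille flow
(centerline $1.5U$, wall stress $6\mu U/H$), a manufactured linear-shear
field (recovered to round-off), closed-form circular-segment areas and
polyhedron volumes, hand-enumerated percentile sites, mirror symmetry, and
the $\tau \leftrightarrow Q$ algebra at machine precision. Grid-convergence
accuracy is quantified the way practitioners do it: Richardson comparison of
nested resolutions (16/32/64 cells across the channel), whose observed order
sits between 1 and 2 — interior truncation is second order, the staircase
wall contributes a first-order component and, because walls snap to each
grid's own center lattice, the effective geometry itself moves by $O(h)$
between levels.

Desk-scale problem sizes were chosen so the whole suite runs in minutes on
one core: 32 cells across the vessel for channel studies, a 256-wide grid
(64 cells per diameter, 16 cells/mm) for the refined sidewall-aneurysm run,
coarse 10-cell-diameter cylinders for 3-D checks. The refined aneurysm run
uses a steadiness tolerance of $10^{-5}$: the flow at this Reynolds number is
genuinely steady (the residual decays geometrically, reaching $10^{-5}$ in
roughly 20 convective times), and the wall-stress extrema asserted by the
acceptance checks concern site locations, which freeze early in that decay.

## Known limitations

- 2-D sections cannot carry the swirling sac inflow of real aneurysms; site
  *locations* are robust, stress *magnitudes* are not patient-predictive.
- The staircase wall limits WSS accuracy to first order near oblique
  boundaries; medians over site faces are the recommended statistic.
- Oscillatory shear index and WSS-gradient metrics are out of scope.
- The outlet's zero-gradient + flux-rescale condition is weakly reflective;
  keep at least one diameter of straight vessel downstream of the region of
  interest (the default geometry has two).
- `estimate_convergence_order()` assumes the asymptotic range; at very
  coarse base grids (8 cells across) the estimate is noisy and should be
  read qualitatively.
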