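---
title: "Methods: flow, cell transport and occlusion analysis in a stenotic micro-chamber"
author: "stenoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow, cell transport and occlusion analysis in a stenotic micro-chamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices
behind `stenoflow`, in the spirit of a methods section: what is computed,
under which assumptions, which parameters matter, and what the synthetic
ground truth does and does not establish about real data.

# The chamber

The chamber is a side-view parameterisation of a rectangular micro-channel
of height $H$ and width $W \gg H$ carrying one trapezoidal bump on a wall:
severity $s$ (throat height $h_s = (1-s)H$), ramp angle $\theta$ measured
between the ramp face and the wall plane, flat throat length $L_s$, and
straight sections upstream and downstream. The default parameter set is
the 130 µm-high, 480 µm-wide channel with a 50 % stenosis, 80° ramps and a
150 µm throat; the modelled flow-wise section is 572 µm with 200 µm of
straight channel upstream.

Three parameter conventions were genuinely open and are fixed as follows:

* **Throat length.** $L_s = 150$ µm is the *flat-top* length, excluding
  the two ramp runs $(H-h_s)/\tan\theta \approx 11.5$ µm. With this
  reading the section lengths recompose the 572 µm domain to within about
  1 µm, and that residual is absorbed into the downstream straight section
  (the constructor derives the downstream length from the total).
* **Ramp angle.** $\theta$ is wall-referenced: $80^\circ$ means a
  near-vertical ramp. The axis-referenced reading would give a 65 µm-long
  ramp and could not reproduce a 572 µm section with the stated lengths.
* **As-built preset.** The profilometry-measured heights (131 µm channel,
  65.7 µm throat) are exposed as `variant = "as-built"`; the design values
  are the default. The measured pair still rounds to a 50 % stenosis.

Rasterization marks a cell as fluid iff its centre lies strictly inside
the fluid polygon, and requires at least eight cells across the throat.
The fluid area of the mask converges (first order, stair-step boundary) to
the shoelace area of the polygon; at 0.5 µm the error is below $10^{-4}$.

# Steady flow

## Model

Blood plasma (and, in the continuum approximation, whole blood) is treated
as an incompressible Newtonian fluid: PRP/plasma $\rho = 1025$ kg m$^{-3}$,
$\nu = 1.1\times10^{-6}$ m$^2$ s$^{-1}$; continuum whole blood
$\rho = 1060$ kg m$^{-3}$, $\nu = 3.3\times10^{-6}$ m$^2$ s$^{-1}$. The
flow is driven along a flow-wise periodic domain and matched to a target
volumetric rate $Q$; with $W \gg H$ the problem is solved in the 2-D side
view and $W$ enters only as the scale $Q_{2D} = Q/W$.

The solver neglects inertia (steady Stokes limit). The channel Reynolds
number at working flow rates is $\mathrm{Re} = Q/(W\nu) \approx 4$, so
inertial corrections are a few-percent effect; the computed solution is
exactly fore–aft symmetric about the bump, and the package's own symmetry
check bounds the discrete asymmetry at well under 2 %. Shear-thinning
rheology, pulsatility and clot-growth feedback are out of scope.

## Scheme

The Stokes equations are solved in streamfunction–vorticity form on a
node-centred grid (spacing $\Delta x$, nodes on multiples of $\Delta x$ so
the flat walls lie exactly on grid lines):

$$\nabla^2 \psi = -\omega, \qquad \nabla^2 \omega = 0,$$

with a constant body force dropping out of the vorticity equation. No-slip
walls carry Dirichlet $\psi$: 0 on the solid attached to the $y=0$ wall
and $Q_{2D}$ on the solid attached to the $y=H$ wall — this imposes the
flow rate *exactly*, so no body-force iteration is needed (the linearity
of Stokes flow makes the classic secant iteration on the body force a
one-step identity; the equivalent body force is instead recovered after
the fact from the dissipation balance $g = \Phi/(Q_{2D} L)$ with
$\Phi = \mu\int \omega^2\,dA$, exact for no-slip periodic Stokes flow).
Wall vorticity is closed with the second-order Jensen condition
$\omega_w = (7\psi_w - 8\psi_1 + \psi_2)/(2\Delta x^2)$ along each inward
grid direction, averaged at stair corners. Everything is assembled into
one sparse linear system ($\psi$ and $\omega$ unknowns together) and
solved by sparse LU with the vorticity block scaled by $\Delta x^2$ and a
few steps of iterative refinement; the componentwise backward error is
reported as the residual (typically $10^{-10}$ or better).

Velocities are centred differences of $\psi$; because the flux is the
streamfunction difference between the walls, the discrete flow rate agrees
with $Q$ to $\mathcal{O}(\Delta x^2)$ and is identical across x-stations
to better than 0.1 % at 0.5 µm (0.15 % at 1 µm, dominated by the
stair-step ramp corners).

Verification anchors built into the test suite:

* plane-Poiseuille limit: velocity profile within 1 % ($L_2$), wall shear
  $6Q/(WH^2)$ reproduced through the wall vorticity to machine-level
  truncation error;
* Newtonian closure $\tau_{xy} = \mu\dot\gamma_{xy}$ exact by
  construction; at equal $Q$ the WB/PRP stress ratio is exactly
  $\mu_{WB}/\mu_{PRP}$;
* mid-throat near-wall shear within 10 % of the parallel-plate estimate
  $6Q/(W h_s^2) \approx 7.1\times10^3$ s$^{-1}$ at the PRP working rate.

## Shear extraction

$\dot\gamma_{xy} = \partial u_x/\partial y + \partial u_y/\partial x$ by
centred differences (second-order one-sided at walls); on wall nodes the
converged wall vorticity is used instead ($\dot\gamma_{xy} = -\omega$ on a
flat no-slip wall). In this slot-like geometry the other tensor components
are negligible. Wall profiles sample the fields by bilinear interpolation
along the curve offset 1 µm inward from the wall contour (mitred at
concave corners, exact arc point at convex bump corners). Samples within
2 µm of a ramp corner are *flagged, not suppressed*: the spikes there are
partly artefacts of reporting only the xy component over a stair-step
corner, and downstream analyses should treat them with caution.

$\mathrm{Re}$ uses the channel height and mean velocity $Q/(WH)$ — the
convention that reproduces the order-4 value — with the throat height
available as an alternative characteristic length.

# Cell-transport metrics

Input is a series of timestamped, type-labelled cell positions (snapshot
interval constant to 1 %; 5 ms by default, matching an output cadence of
$10^5$ steps at a $5\times10^{-8}$ s time step). All maps collapse z and
use square (x, y) bins, 2 µm by default.

* **Flux** (s$^{-1}$): presence counts per bin summed over the snapshots
  in the averaging window, divided by the window length. A stationary
  platelet seen in 60 snapshots over 0.30 s contributes 200 s$^{-1}$. The
  presence-event reading (rather than unique-cell counting) is adopted
  because the definition divides a per-snapshot count by total time.
* **Residence time** (s): per platelet and visit start, the first time lag
  at which the cumulative path length of the trajectory reaches one
  platelet diameter (2 µm), interpolated linearly inside the crossing
  step; x-displacements are minimum-image unwrapped across the periodic
  seam. Each visit is binned at its start position; visits that never
  translocate the diameter inside the window are censored at the window
  end and tallied separately — with a 0.3–0.35 s window, recirculation-
  zone platelets are necessarily censored, so the censored map is part of
  the result, not noise.
* **Red-cell volume fraction**: mean per-snapshot count × cell volume /
  bin volume, clipped to [0, 1]. Cell volumes default to literature
  values (90 µm³ per red cell, 6 µm³ per platelet) and are configurable.
* **Cell-depleted layer**: per x-column, the distance from the wall to the
  first bin centre whose volume fraction exceeds a threshold, linearly
  interpolated between the bracketing bins and capped at the local lumen
  half-height. The 1 % rule is read as *relative* to the column's core
  (maximum) fraction by default, with an absolute mode exposed, since
  either reading is defensible; the two differ only when the core
  haematocrit departs strongly from unity scaling. All-zero columns
  return the cap, flagged. The threshold-crossing estimator carries a
  discretization bias of up to one bin width toward the wall; recovery is
  therefore validated to within one bin.

# Occlusion pipeline

* **Evaporation correction** subtracts the paired reference-dish signal,
  linearly resampled to the trace times:
  $m' = m - (r - r_0)$.
* **Flow rate** is the least-squares mass slope over a pre-occlusion
  window divided by $\rho$ (×10⁹ for µl/s).
* **Occlusion time**: the trace maximum marks occlusion; when the balance
  plateaus, the plateau's temporal centre is taken. Numerically the
  plateau level is estimated as the median of samples within a
  noise-adaptive band (4× a robust `mad(diff(m))`-based noise scale, never
  narrower than the user tolerance $\varepsilon$, default twice a 1 mg
  balance resolution), so a single noise spike can neither inflate the
  level nor fragment the plateau. Design choice for a boundary case the
  plateau-centre rule does not define: a plateau running to the final
  sample returns the plateau *start* (centre would depend on when the
  recording stopped), flagged `plateau_open`; a trace still rising at the
  last sample is flagged `right_censored`.
* **Intensity profile**: the occlusion frame is averaged over the
  annotated channel width, min–max normalized over the channel span, and
  aligned so the upstream stenotic corner (the right border of the
  contraction area) is $x = 0$. PRP aggregates darken rather than
  brighten, so PRP profiles are inverted; invert-then-normalize is the
  default with the reverse order exposed (they differ only in the min–max
  convention). Flat frames are flagged degenerate and yield no distance.
* **Occlusion distance**: $x$ of the global intensity maximum, first
  maximum on ties (flagged). Corner annotation is a coordinate file (4
  corners when the steep ramps collapse to single edges in top view, 8
  when contraction and expansion areas are resolved); the pixel scale can
  be derived from the annotated corner spacing against the known throat
  length when the pixel size is not recorded.

# Synthetic ground truth

The generators emulate the *statistical structure* of cell-resolved
simulation output and bright-field recordings; they do not simulate
mechanics.

* **Cell snapshots**: red-cell y-positions are uniform in the core and
  zero within a prescribed cell-free-layer width $\delta^*$ of each wall
  (default 5 µm); platelets carry a platelet-free sliver at the wall
  (0.5 µm), an $f$-fold enriched band over the first 5 µm beyond it
  ($f = 2$ for whole blood, 1 for PRP), optional quarter-height bands, and
  are uniform elsewhere. Cells advect in x with the local flow velocity;
  transverse positions are re-drawn each snapshot as base position plus
  jitter *reflected at the type's support boundary*, which keeps the
  prescribed sharp edges and marginated profile stationary — emulating the
  restoring forces that hold a quasi-steady marginated distribution. A
  consequence worth knowing when designing tests: platelet y-positions
  persist across snapshots, so the statistical power of any band-occupancy
  estimate scales with the *cell count*, not the snapshot count. A second
  consequence: with equal platelet counts, enriching the whole-blood wall
  bands dilutes its core, so the measured WB/PRP wall-band flux ratio is
  ≈ 1.86 rather than exactly 2 — inside the ±15 % recovery band used in
  the tests.
* **Mass traces**: $m(t) = \rho Q \min(t, t^*)$ plus evaporation drift and
  Gaussian balance noise, with an optional smooth quadratic ramp-down of
  the flow before $t^*$; the paired reference carries drift and noise
  only. Defaults: 1 Hz sampling, 1 mg noise, $-2\times10^{-8}$ kg s$^{-1}$
  evaporation.
* **Image stacks**: 2 Hz frames at 2 µm/px over a 600 µm field; the
  channel is a brighter band between darker margins, the stenotic borders
  are marked by ticks *outside* the averaged channel rows (so the
  annotation landmarks exist without biasing the width-averaged profile),
  and the clot is a separable Gaussian (15 µm × 120 µm) growing linearly
  in amplitude (0.4 at occlusion) until $t^*$ — added for WB, subtracted
  for PRP — plus per-pixel Gaussian noise (0.01).

What passing the synthetic tests shows: the estimators recover programmed
flow rates within 1 %, occlusion times within one balance sample, clot
positions within one pixel in both modalities, prescribed depletion widths
within one bin, and the margination enhancement factor within the stated
bands. What it does not show: correctness under real-data pathologies the
generator does not emulate — uneven illumination, focus drift, debris,
non-Gaussian balance disturbances, clot shapes far from Gaussian, or
margination profiles unlike the prescribed piecewise form.

# Problem sizes and costs

The acceptance computation rasterizes the default chamber at 0.5 µm
(1144 × 260 cells, ≈ 2.6 × 10⁵ fluid nodes; sparse LU a few minutes on one
CPU). The test suite solves that problem once, plus straight-channel
problems at 1–2 µm for the Poiseuille anchors; cell-metric tests use
10³–5 × 10⁴ cells over 10–60 snapshots; imaging tests use 300 × 300 px
stacks of 60–150 frames. Numerical tolerances asserted in the suite are
stated next to each check, never looser than the figures quoted above.

# Known limitations

* 2-D side-view flow with $W$ as a scale factor; no z-varying geometry.
* Stokes limit: the weak inertial fore–aft asymmetry present at
  $\mathrm{Re}\approx4$ is deliberately absent.
* Stair-step rasterization makes near-corner shear locally first-order;
  corner samples are flagged rather than corrected.
* The cell generators prescribe margination statistically; they cannot
  validate mechanistic margination models, only the estimators applied to
  their output.
* Bright-field intensity carries no aggregate-height information; the
  occlusion distance is a planar quantity.
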