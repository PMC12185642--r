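---
title: "Hemodynamic descriptors and 0D boundary-condition calibration for arteriovenous grafts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamic descriptors and 0D boundary-condition calibration for arteriovenous grafts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avgflow)
```

## Scope and intent

`avgflow` post-processes time-resolved CFD-style fields from patient-specific
arteriovenous graft (AVG) simulations and supports the boundary-condition side
of such simulations with a lumped-parameter (0D) network model. It deliberately
does **not** contain a 3D flow solver, mesh generator or image-segmentation
step: velocity fields on tetrahedral meshes and wall-shear-stress (WSS) fields
on triangulated lumen surfaces are consumed as solver output (legacy-ASCII VTK
files plus a JSON series manifest), and every downstream quantity — turbulence,
helicity and near-wall descriptors, percentile thresholds, critical-area maps —
is computed here, reproducibly and testably.

All internal units are SI (m, s, Pa, m^3/s, kg/m^3). Clinical pressures in
mmHg are converted at 1 mmHg = 133.322 Pa.

## The 0D network and Windkessel calibration

The vascular domain is reduced to a directed graph of segments, each carrying
the pressure-drop law

$$\Delta P = a\,Q|Q| + b\,Q + L\,\frac{dQ}{dt},$$

where the quadratic and linear coefficients $(a, b)$ come from fitting
$\Delta P = aQ^2 + bQ$ (zero intercept: no drop at no flow) to steady
pressure-drop/flow samples of each anatomical section, and the inertance is
$L = \tfrac{4}{3}\rho\,l/A$ for a segment of length $l$ and lumen area $A$
(the 4/3 factor is the flat-profile momentum correction for large arteries).
The quadratic term is implemented as $aQ|Q|$ rather than $aQ^2$ so that the
drop opposes reversed flow; retrograde flow is physiologically possible in
dialysis-access circulation even when a particular patient does not exhibit
it. Boundary nodes are terminated by one prescribed inflow waveform, fixed
venous pressure sinks (default 8 mmHg, a typical central venous pressure), or
three-element Windkessel (WK3) models with proximal resistance $R_p$, distal
resistance $R_d$ and compliance $C$:

$$P = P_c + R_p Q, \qquad C\,\frac{dP_c}{dt} = Q - \frac{P_c - P_\mathrm{ref}}{R_d}.$$

### Time integration

The coupled system of junction mass balances (algebraic), segment laws and
WK3 state laws is integrated with backward Euler and a full Newton solve per
step (analytic Jacobian; the only nonlinearity, $aQ|Q|$, has derivative
$2a|Q|$). Rows and columns are rescaled by characteristic flow and pressure
magnitudes so the iteration matrix stays well conditioned across the ~18
orders of magnitude separating resistances (Pa s/m^3) from flows (m^3/s).
Convergence tolerance is 1e-10 on the scaled residual, which directly
guarantees junction mass conservation to 1e-10 of the inflow magnitude — one
of the tested invariants. The scheme is first order; halving the time step
changes last-cycle systolic pressure by well under 0.2% at the default
dt = 1 ms.

**Initial state.** By default the simulation starts from the steady solution
at the cycle-mean inflow rather than from rest. Calibrated Windkessel
compliances routinely give $R_d C$ time constants much longer than one
cardiac period; a cold start would then drift for tens of cycles, never
meeting the periodicity criterion, and any quantity read off "the last cycle"
would be transient-contaminated. Starting at the mean-flow steady state
leaves only the fast intra-cycle dynamics, and the cyclic periodicity
criterion — < 1% change in peak systolic pressure between subsequent cycles,
the same rule used for the 3D simulations this model supports — is typically
met on the second cycle. The physical charging transient remains available
with `init = "zero"`, which is how the step-response test verifies the
$\tau = R_d C$ closed form to 0.5%.

### Calibration

`calibrate_wk3()` automates what is usually manual tuning. The same
$(R_p, R_d, C)$ triplet is applied at every arterial outlet (when no clinical
flow-split between individual outlets is available, the branch geometry sets
the inter-outlet split) and adjusted to meet two targets: the measured
systolic (peak) inlet pressure, and the cycle-mean fraction of inlet flow
leaving through the arterial outlets (target 27% with a ±5% band in the
shipped synthetic study, matching a typical DUS-derived intra-access flow of
73%). Two structural facts make the problem well posed: in the periodic state
the compliance passes no net flow, so the *mean* split is controlled by the
resistances alone; and the pulse amplitude at the inlet is controlled by $C$
and the $R_p\!:\!R_d$ partition. The procedure is therefore a deterministic
steady-state root-find on the total outlet resistance (seeding the split,
with $R_p\!:\!R_d$ initially at the classical 10:15 proportion) followed by
bounded Nelder–Mead minimisation over $\log(R_p, R_d, C)$ of the equally
weighted two-term relative objective (pressure mismatch, split mismatch).
There is no randomness anywhere: calibrating twice returns identical
parameters. Infeasible targets (e.g. a requested split of 100% with a finite
venous path) are detected at the seeding stage and reported with the
achievable bound.

Printed WK3 values quoted for such models in the clinical literature often
omit units; this toolkit never assumes any, and requires explicit SI values
in configs.

## Volume descriptors

Fluctuating velocity is defined as the deviation from the single-cycle time
mean, $\mathbf{v}' = \mathbf{v} - \bar{\mathbf{v}}$, and the turbulent
kinetic energy at an instant is
$TKE = \tfrac{1}{2}\rho\left((u')^2 + (v')^2 + (w')^2\right)$ (J/m^3),
conventionally reported at peak systole, which the pipeline takes as the
argmax of the inflow waveform. This single-cycle definition conflates
pulsatile and genuinely turbulent content — with one simulated cycle the two
cannot be separated — and uses resolved fluctuations only (no RANS-model
$k$ is added). Both caveats matter when comparing absolute TKE levels across
studies.

Vorticity is reconstructed per tetrahedron from linear shape functions
(constant gradient per cell, curl of that gradient), then volume-averaged to
nodes. The reconstruction is exact for affine velocity fields, which is what
the rigid-rotation and simple-shear oracles test.

Helicity descriptors over a region $V$ and cycle $T$:

$$h_1 = \frac{1}{TV}\int_T\!\!\int_V \mathbf{v}\cdot\boldsymbol{\omega}\;dV\,dt,
\qquad h_2 = \frac{1}{TV}\int_T\!\!\int_V |\mathbf{v}\cdot\boldsymbol{\omega}|\;dV\,dt,$$

with $h_3 = h_1/h_2 \in [-1, 1]$ the signed helical rotation balance and
$h_4 = |h_3|$ its unsigned form ($h_3 = h_4 = 0$ by convention when
$h_2$ is below 1e-12, i.e. the flow is effectively helicity-free). Time- and
volume-averaged normalisation (units m/s^2) was chosen so values are
comparable across regions of different size. Local normalised helicity
$LNH = \mathbf{v}\cdot\boldsymbol{\omega}/(|\mathbf{v}||\boldsymbol{\omega}|)$
is the alignment cosine in $[-1, 1]$, set to 0 where $|\mathbf{v}||\boldsymbol{\omega}| <$
1e-12 (SI). Volume quadrature is per-cell midpoint (arithmetic mean of the
four nodal densities times cell volume); on a refined cylinder it agrees with
a Monte-Carlo integral of an analytic field to better than 1%.

## Wall descriptors

With $\boldsymbol{\tau}(t)$ the WSS vector at a surface node (projected onto
the local tangent plane on load; the removed normal component is recorded),
$T$ the period and $\mathbf{n}$ the outward unit normal:

* **TAWSS** $= \frac{1}{T}\int_0^T |\boldsymbol{\tau}|\,dt$ — low values mark
  remodelling-prone lumen.
* **OSI** $= \frac{1}{2}\left(1 - |\int_0^T \boldsymbol{\tau}\,dt| / \int_0^T |\boldsymbol{\tau}|\,dt\right)
  \in [0, 0.5]$ — direction reversal over the cycle (0 where the shear
  integral is below 1e-9 Pa s).
* **transWSS** $= \frac{1}{T}\int_0^T |\boldsymbol{\tau}\cdot(\mathbf{n}\times\mathbf{m})|\,dt$
  with $\mathbf{m}$ the unit cycle-mean WSS vector — multidirectionality.
  Where the mean WSS magnitude is below 1e-9 Pa the mean direction is
  undefined (perfectly reversing shear); those nodes are flagged and assigned 0.
* **Unit-WSS divergence**: the WSS direction field $\mathbf{u} = \boldsymbol{\tau}/|\boldsymbol{\tau}|$
  (zeroed below 1e-6 Pa) is interpolated linearly per triangle and its
  in-plane divergence $\sum_i \mathbf{u}_i\cdot\nabla\phi_i$ computed per cell
  — exact for fields affine within a flat patch, verified against the
  analytic $1/r$ divergence of a radial field on an annulus.
* **TSVI** $= \sqrt{\frac{1}{T}\int_0^T (D - \bar{D})^2\,dt}$ (1/m), the RMS
  of the unit-WSS divergence $D$ about its own cycle mean, per cell —
  unsteadiness of the contraction/expansion pattern the WSS exerts on the
  near-wall flow.

All time integrals are trapezoidal with a wrap segment closing the period
(sample series need not repeat the first sample at $t = T$). Cell-based TSVI
is transferred to nodes by area-weighted averaging only for reporting.
The tested invariants: $0 \le OSI \le 0.5$, $transWSS \le TAWSS$, all four
indices invariant under rigid rotation of the whole dataset, and agreement of
the trapezoidal integrals with a 10x-oversampled quadrature to 0.1% on smooth
histories.

## Thresholds, critical areas, similarity

Critical-area mapping follows the percentile convention used in near-wall
hemodynamics studies: one *patient-specific* threshold per index, computed
over the whole-domain luminal distribution — the 33rd percentile for
"low-is-adverse" indices (TAWSS) and the 66th for "high-is-adverse" ones
(OSI, transWSS, TSVI) — then applied within each region of interest (ROI).
Percentiles are **area-weighted**: the threshold is the smallest value at
which the cumulative element area reaches the requested fraction of total
area, with linear interpolation between adjacent distinct values (tied values
are aggregated first). Masking uses strict inequality; for continuous fields
the choice at equality has measure zero and is documented purely for
reproducibility. Thresholding operates on cell-based values with cell areas
by default (node support is available and tagged), since areas are
unambiguous for cells. Per-ROI output is the percentage of ROI area flagged
critical, the machine twin of the usual per-index/per-ROI table.

Overlap between two critical-area maps (e.g. across boundary-condition
strategies) is quantified with an area-weighted Dice coefficient,
$100 \cdot 2\,\mathrm{area}(A\cap B)/(\mathrm{area}(A)+\mathrm{area}(B))$,
100 when both maps are empty. Dice was chosen because it is symmetric,
bounded and area-aware; the formula is isolated in `similarity_index()` so an
alternative overlap definition can be swapped in.

## The synthetic-data generators

Fixtures exist so every computation can be checked against a closed form
without patient data or a commercial solver. They emulate canonical flow
regimes, not patient anatomy:

* **Structured cylinder mesh** (extruded disk triangulation; prisms split into
  tetrahedra with the smallest-index diagonal rule, giving a deterministic,
  conforming mesh) with its lateral wall surface. Analytic checks: summed tet
  volume vs $\pi R^2 L$ and wall area vs $2\pi R L$, both within 1% at the
  refined resolution (32 circumferential nodes).
* **Womersley pulsatile pipe flow**: steady Poiseuille component plus
  classical oscillatory profiles per flow harmonic, scaled so the
  cross-section integral reproduces the prescribed flow; wall shear is the
  analytic radial derivative. Requires constant (Newtonian) viscosity — the
  Womersley solution does not exist for a shear-thinning fluid — and is
  accurate to Womersley numbers of about 20 (power-series Bessel evaluation
  of complex argument, cross-checked against `besselJ` on the real axis).
* **Rigid-rotation helical flow** $\mathbf{v} = (-\Omega y, \Omega x, W)$
  with closed forms for vorticity, helicity density $2\Omega W$ and
  $LNH(r) = W/\sqrt{\Omega^2 r^2 + W^2}$.
* **Prescribed WSS patterns** (unidirectional-pulsatile, reversing, rotating,
  biaxial, divergence-switching) with documented closed-form TAWSS, OSI,
  transWSS and TSVI values.
* **Toy six-segment AVG network**: inlet (absorbing the anastomosis section),
  three WK3-terminated arterial branches of different calibre, an
  arterial-plus-venous graft segment and a venous restriction draining to an
  8 mmHg sink. Default coefficients are plausible for graft-calibre vessels
  at about 1 L/min access flow; the shipped inflow is a two-harmonic positive
  pulse with mean 1.5e-5 m^3/s (0.9 L/min) and period 0.8 s.
* **Carreau–Yasuda viscosity**,
  $\mu = \mu_\infty + (\mu_0-\mu_\infty)\left[1+(\lambda\dot\gamma)^a\right]^{(n-1)/a}$,
  with classical blood defaults ($\mu_0 = 0.056$ Pa s, $\mu_\infty = 0.00345$
  Pa s, $\lambda = 3.313$ s, $a = 2$, $n = 0.3568$), all overridable.

What passing these fixtures shows — and what it does not: the descriptor
arithmetic, quadrature, thresholding and calibration logic are correct on
fields whose answers are known exactly. The fixtures are laminar, smooth and
geometrically idealised; they say nothing about turbulence modelling, mesh
convergence of a 3D solver, or segmentation fidelity on real anatomy.

## Numerical choices and problem sizes

Degenerate-input conventions are collected here: LNH floor 1e-12; OSI shear
floor 1e-9 Pa s; WSS normalisation floor 1e-6 Pa; transWSS degenerate-node
convention value 0 plus flag; helicity-balance floor 1e-12 m/s^2; percentile
ties aggregated before interpolation; strict inequality at thresholds. Cubic
splines use periodic end conditions for periodic waveforms and natural
otherwise — natural end conditions perturb even a polynomial signal near the
boundary knots (the second derivative is forced to zero), which is why the
resampling tests assert exactness at knots and accuracy in the interior
rather than global polynomial reproduction.

The test suite and the acceptance analysis run at deliberate desk scale:
cylinders up to 32 x 8 x 12 resolution (~18k tetrahedra), series of 8–512
time samples, and 0D runs at dt = 1–2 ms over a 0.8 s cycle with early
stopping at cyclic periodicity. The calibration study uses dt = 2 ms inside
the optimiser and verifies at dt = 1 ms. These sizes were chosen so the whole
validation cycle stays interactive while every quantitative check retains a
demonstrated discretisation margin.

## Known limitations

* One cycle of data means pulsatility and turbulence are not separable in the
  TKE definition (documented above).
* The 0D calibration identifies the *targets*, not unique parameters: with
  two targets and three parameters, different $(R_p, R_d, C)$ triplets can
  satisfy the same pressure/split pair. Only target attainment is tested.
* The Similarity Index is a Dice coefficient by design choice; other overlap
  definitions exist and can be plugged in.
* VTK support covers the legacy-ASCII subset this toolkit writes
  (tetrahedra/triangles, scalars/vectors/normals); XML/binary VTK is out of
  scope.
* Surface divergence assumes per-triangle flatness; strongly curved, coarse
  walls increase the discretisation error of divergence-based quantities
  (TSVI inherits this).
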