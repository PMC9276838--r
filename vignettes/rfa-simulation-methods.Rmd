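---
title: "Simulating radiofrequency ablation: models, numerics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating radiofrequency ablation: models, numerics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rfasim)
```

## The physical problem

Radiofrequency ablation (RFA) destroys tissue by resistive (Joule)
heating: an umbrella-style multi-tine electrode is deployed inside the
target, RF current flows from the tines through the tissue to a return
pad, and the tissue around the tines is heated past the point of
protein denaturation. The clinical question the simulation answers is
*what volume of tissue did this particular ablation actually destroy*,
given the electrode's measured pose and the power the generator
actually delivered. `rfasim` implements this simulation together with
the validation instruments needed to test it: scene builders for bench
phantoms and CT-derived electrode poses, segmentation of "true"
ablation boundaries, and surface-distance error metrics against both
the simulation and the manufacturer's chart model.

The physics is a one-way coupled chain of three models sharing one
structured grid.

### Electrical model

At RF frequencies (~500 kHz) and centimetre scales, tissue behaves
resistively and the potential satisfies the quasi-static conduction
equation

$$ \nabla \cdot (\sigma \nabla V) = 0, $$

with $V = V_0$ on the energized tines, $V = 0$ on the return pad, and
zero normal current on insulated surfaces. The dissipated power density
$q = \sigma |\nabla V|^2$ is the heat source for the thermal model.

The generator's impedance-control loop is *not* simulated. The
generator logs applied power at 1 Hz over its serial port; that
recorded trace is the simulation's driving signal. Each control step
the unit-potential solution is rescaled so the domain-integrated
dissipated power equals the recorded sample exactly (power scales with
$V_0^2$, so the potential scales with the square root of the power
ratio). Because the discrete power is computed from the same link
conductances as the solve, the power match is exact to solver
round-off, and the energy bookkeeping downstream inherits that
exactness.

Temperature-dependent conductivity
$\sigma(T) = \sigma_0 (1 + \beta (T - T_0))$ is available
(`beta_sigma`); it is off by default ($\beta = 0$), and when enabled
the potential is re-solved only when the temperature field has drifted
more than `resolve_dT` (default 5 °C) since the last solve, because a
full factorization per step buys nothing while $\sigma$ is frozen.

### Thermal model

Tissue temperature follows the Pennes bioheat equation

$$ \rho c \frac{\partial T}{\partial t}
   = \nabla \cdot (k \nabla T) + q
   - \omega \rho_b c_b (T - T_a), $$

where $\omega$ (1/s) is the volumetric perfusion rate, $\rho_b, c_b$
are blood properties and $T_a$ the arterial temperature. Perfusion is
applied in tissue-class cells only: agar phantom runs use
$\omega = 0$ (the phantom has no perfusion — which is exactly why the
bench experiments can validate the electrical–thermal chain in
isolation), while the liver preset uses $\omega = 6.4\times10^{-3}$/s,
a standard hepatic figure in the RFA modelling literature.

**Vessels.** Large vessels act as heat sinks. The lumen is excluded
from the conducting solid and the vessel wall carries a convective
Robin boundary $q'' = h (T_\text{wall} - T_\text{fluid})$. The film
coefficient comes from the internal-flow correlation: with the bench
channel (5 mm diameter, 10.5 cm/s water) the Reynolds number is
$Re = vd/\nu \approx 525$, safely laminar, so the constant-wall
Nusselt number $Nu = 3.66$ applies and
$h = Nu\,k_f/d \approx 439$ W/m²K. Faster flows switch to
Dittus–Boelter. Zero flow degrades gracefully: the lumen rejoins the
domain as a stationary water column and heat enters it by conduction
only. A resolved-advection lumen model is deliberately out of scope;
the Robin wall is the standard, testable choice, and the monotone
heat-sink property (vessel-adjacent temperatures never exceed the
matching no-vessel run) is asserted in the test suite.

**Evaporation.** Near 100 °C tissue water vaporizes and temperature
plateaus. This is modelled with an enthalpy band: between 99 and
101 °C the effective volumetric heat capacity is augmented by
$\rho\, w\, L / \Delta T_\text{band}$ ($w$ = water fraction, $L$ =
latent heat), so traversing the band absorbs exactly the latent heat
of the tissue water. A ceiling clamp at band top + 5 °C absorbs
residual overshoot and books the clamped energy as vented. The plateau
duration under constant heating has a closed-form value (latent energy
over power), which the tests check against the simulated history. The
band formulation is a documented stand-in for whatever the commercial
library does internally; its two knobs (band width, water fraction)
are configuration, not code.

**Time discretization.** Backward Euler at a solver step `dt`
(default 0.5 s) with the 1 Hz power trace held by zero-order hold.
Backward Euler is unconditionally stable, which matters because the
interesting runs combine a 1.5 mm grid with 300 s of simulated time;
the price is first-order accuracy in time, and the suite verifies that
halving `dt` moves the final field by a first-order amount with no
oscillation. The evaporation nonlinearity is handled by an
enthalpy-corrected Picard iteration (the classic Voller construction):
each linear solve's delivered per-node energy is converted back to a
temperature through the exact piecewise-linear enthalpy inverse, and
the apparent capacity is re-derived as the secant at that consistent
point. A pointwise lagged capacity 2-cycles across the enthalpy kink
at band entry and silently loses latent heat; the corrected iteration
is exact after one correction for uniform heating and keeps the energy
ledger tight through the plateau.

An energy ledger accumulates input (Joule heat), outputs (perfusion
sink, vessel-wall convection, clamp venting) and storage (sensible +
latent, using the same lagged capacity as the step), so closed systems
balance to solver tolerance and full phantom runs close within a
fraction of a percent.

### Damage model

Cell death is an Arrhenius rate process: the damage integral

$$ \Omega(x) = \int_0^t A \exp\!\left(-\frac{E_a}{R\,T(x,\tau)}\right)
   d\tau $$

is accumulated trapezoidally in time alongside the thermal march
(temperatures converted to kelvin in one place). $\Omega = 1$
(≈63 % cell kill) defines the ablation boundary by convention;
$\Omega = 4.6$ (≈99 %) is available. The defaults
$A = 7.39\times10^{39}$ 1/s, $E_a = 2.577\times10^5$ J/mol are
whole-liver coagulation kinetics from the thermal-damage literature;
the agar–albumin phantom is read with the same kinetics (albumin
denaturation is itself a protein-denaturation process; its exact
constants are not published for this recipe, so they are configurable
rather than hard-coded). The ablation surface is the $\Omega$
iso-surface extracted by marching tetrahedra, with the enclosed volume
from the divergence theorem.

## Discretization and solvers

The reference spatial discretization is a cell-centered finite-volume
scheme on a uniform hexahedral grid with harmonic-mean face
conductances — the scheme is exact for piecewise-linear fields and for
series-slab conduction, symmetric positive-semidefinite, conservative
(zero interior row sums) and monotone (discrete maximum principle).
The commercial pipeline this emulates used graded tetrahedral FEM
meshes; element type is not what the physics contract cares about, and
the structured grid keeps assembly, time stepping and iso-surfacing
simple and fast. Linear systems are solved matrix-free by
Jacobi-preconditioned conjugate gradients in compiled code; thermal
steps warm-start from the previous temperature and converge in a
handful of iterations.

Two features deal with the fact that electrode features (0.4 mm tine
wires, the 1 mm analytic sphere) live at or below the grid scale:

* **Embedded boundaries.** Nodes inside the energized surface are
  Dirichlet nodes; grid links crossing the surface are scaled by the
  sub-cell interface fraction obtained from the signed distance field
  (`theta` in the assembler), so the boundary position enters with
  sub-cell accuracy instead of snapping to the nearest node. Tines are
  thickened to an effective radius of `max(0.4 mm, 0.6 h)` — a
  documented resolution-dependent approximation for sub-grid wires.

* **Near-field subgrid calibration.** Most of an electrode's
  spreading resistance sits within a cell or two of its surface, where
  any uniform lattice is least accurate. Before the main solve, a box
  around the electrode is cut out and the local conduction problem is
  solved twice — once on the run grid and once at four-fold finer
  spacing, both with unit electrode potential and grounded box faces —
  and the coarse electrode couplings are scaled so the two local
  conductances match. The common outer boundary condition cancels to
  first order, so the factor captures exactly the coarse grid's
  near-field deficit. This is the same subgrid-upscaling idea used for
  transmissibility corrections in reservoir simulation; it is
  deterministic and never consults an analytic solution. On the
  concentric-sphere benchmark it reduces the spreading-resistance
  error at 1 mm spacing from ~8 % to ~3 %, converging further under
  refinement.

Large electrical solves (> 1.5 M nodes) additionally warm-start from a
solve at twice the spacing, prolonged trilinearly (a two-grid
cascade), which roughly halves the iteration count.

## Validation instruments

* **Segmentation.** Scanned phantom sections show denatured
  (opaque-white) agar against a darker background. A region-based
  level set of the Chan–Vese type, initialized from an isodata
  threshold, evolves under the two-region intensity competition plus a
  curvature penalty; the zero level set is extracted with sub-pixel
  interpolation. On seeded synthetic discs with realistic noise the
  recovered boundary is accurate to a fraction of a pixel. 3D "true"
  volumes (manually segmented contrast CT in the animal workflow)
  enter as label masks or meshes — re-implementing an interactive
  segmentation workstation is a non-goal.

* **Equidistant sampling.** 2D contours are resampled to exactly
  *n* points equally spaced in arc length (the 64-point protocol).
  Surfaces get approximately *n* evenly distributed points: rejection
  of area-weighted random candidates against a Poisson-disk radius,
  with the radius tuned by bisection until the accepted count lands
  within 1 % of the target. On a unit sphere the nearest-neighbour
  spacing matches the even-covering value $\sqrt{4\pi/n}$ with a
  coefficient of variation under 10 %.

* **Surface error.** The error metric is directional by definition:
  distances from points sampled on the *true* boundary to the nearest
  point of the *model* surface (point-to-triangle, never
  vertex-only; compiled, with a brute-force R oracle in the tests).
  The reverse direction is available but never silently substituted.
  Reports carry per-point distances plus mean and max; "average max"
  across a batch of ablations means the per-ablation max averaged over
  cases.

* **Chart comparator.** The manufacturer's expected-ablation chart is
  modelled as two half-ellipsoids sharing the equatorial disc at the
  electrode tip: for the 3 cm probe, radial semi-axis 15 mm, distal
  depth 16 mm, proximal depth 9 mm. Only the 3 cm row ships; other
  diameters require a user-supplied table. Paired per-case errors
  (simulation vs chart, same sampled points) feed a classical paired
  two-sided t-test; a zero-variance difference vector is reported as
  degenerate rather than yielding a silent p-value.

* **Tine detection and registration.** CT-like volumes are
  thresholded at a metal-range cutoff; metal voxels are clustered by
  azimuth about the shaft axis (tines converge at the tip, so a
  near-axis cone is excluded), and each cluster is reduced to an
  ordered centerline by binning along the distance-from-tip parameter,
  which is monotone along an umbrella tine. Detected tines are matched
  to ideal ones by azimuth and their maximum deviation reported —
  deployed tines can deflect several millimetres from ideal, and the
  electrode model accepts measured paths. Rigid registration between
  ideal and measured electrodes is a least-squares (Kabsch) fit over
  the tip plus arc-length-resampled tine points; collinear
  configurations are rejected as degenerate.

## The synthetic-data generators

No bench scans or animal CTs are distributed, so every input is
emulated with known ground truth:

* **Phantom scenes** mirror the bench recipe: a two-liter beaker
  (radius 65 mm, agar fill 145 mm — 1.9 L), return pad on the bottom,
  4 cm umbrella electrode on the axis inserted from the top, and an
  optional straight vertical 5 mm channel at 25/30/35 mm from the
  shaft with 10.5 cm/s water flow. The offset convention is
  shaft-axis-to-*centerline* (the bench description does not say wall
  or centerline; a flag switches to wall). The electrode tip sits
  85 mm above the pad so the ablation is far from both pad and free
  surface.

* **Ideal tines** are circular arcs in planes through the shaft axis,
  equally spaced in azimuth, leaving the tip radially and curving
  distally; at full deployment the maximum radial extent equals half
  the nominal diameter, and partial deployment truncates the arcs so
  the extent scales linearly. The vendor's true curve is proprietary;
  this family reproduces the umbrella appearance and the
  nominal-diameter constraint, which is what the field solution
  depends on.

* **Power traces** emulate a recorded generator log: ramp from 20 W
  to an 80 W plateau over 60 s, held for a 5-minute ablation, with
  small seeded jitter and an optional roll-off dip. The plateau level
  was chosen once so that the simulated no-vessel phantom ablation
  reaches roughly the electrode's nominal 4 cm diameter, matching what
  the device chart leads one to expect from a completed protocol; it
  is a fixture parameter, not a fit.

* **Slice images** rasterize a known boundary at 0.25 mm/px with a
  0.5 contrast step, 1 px Gaussian blur and seeded Gaussian noise
  (σ = 0.05) — representative of a flat-bed scan of an agar section.
  **Tine CT volumes** paint the (optionally deflected) tine
  centerlines at metal intensity into seeded soft-tissue noise at
  0.5 mm voxels.

All generators are bit-reproducible under a fixed seed. What they do
*not* emulate: scanner illumination gradients and cutting artefacts in
real sections, partial-volume and beam-hardening effects around real
tines, perfusion heterogeneity in real liver, and tissue property
drift during heating. Passing the synthetic suite therefore
demonstrates the pipeline's internal correctness (solvers against
closed forms, metrics against constructions, end-to-end determinism),
not bench-level accuracy on new data.

## Problem sizes and numerical defaults in the tests

The test and acceptance workloads are sized for a single CPU: the
concentric-sphere benchmark runs at 1 and 0.5 mm spacing (the latter
~15 M cells, solved in well under two minutes via the cascade); the
heat-sink comparison runs the four phantom cases (no vessel and
offsets 25/30/35 mm) at 1.5 mm and 1 s steps; the full-physics
determinism and energy-ledger checks run one 5-minute phantom at
1.5 mm and 0.5 s. Solver tolerances are 1e-6 to 1e-8 relative
residual depending on context; the power-matching identity holds to
1e-12 regardless because it is enforced by rescaling, not by solving.

## Known limitations

* No vapor mass transport: the enthalpy band localizes the latent
  sink at the boiling site. A `--vapor-transport` extension is
  reserved but unimplemented; bench evidence suggests vapor transport
  tightens in-vivo maxima.
* No tissue shrinkage, deformation or property drift with damage.
* The Robin vessel wall ignores axial enthalpy transport in the
  lumen; for short residence times (10.5 cm/s through a 15 cm
  channel) the fluid bulk temperature rise is small, making the
  constant-$T_\text{fluid}$ wall a good approximation.
* Single uniform perfusion rate per run — the in-vivo error budget in
  this field is dominated by unmeasured perfusion heterogeneity.
* The structured grid represents tine wires through an effective
  radius; sub-millimetre near-tine temperature texture is not
  resolved, only the integrated deposition (which the calibration
  pins) matters downstream.
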