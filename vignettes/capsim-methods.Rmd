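---
title: "Simulating nanoparticle transport in capillaries with capsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nanoparticle transport in capillaries with capsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsim)
```

## The model

`capsim` is an agent-based simulator of nanoparticle transport in a single
capillary. The capillary is a hollow cylinder (default radius 4000 nm, an
8 um vessel; length 50 um, axially periodic) with no-slip walls. Three kinds
of agents interact with a quasi-static flow field:

* **Red blood cells** — rigid, radially centred, axisymmetric
  parachute-shaped obstacles. They move axially at the speed at which the
  net hydrodynamic force on them vanishes, which the pressure gradient and
  suspension viscosity determine.
* **Nanoparticles** — spheres of 10-160 nm diameter advancing by an
  overdamped update: laminar displacement `u(x) dt` interpolated from the
  flow field, plus an isotropic Gaussian Brownian displacement with
  per-axis standard deviation `sigma = sqrt(2 D dt)`, where
  `D = k_B T / (6 pi mu r)` is the Stokes-Einstein diffusion coefficient.
  The vessel wall reflects particles specularly; particles and cells may
  not overlap (excluded volume by projection to tangential contact).
* **Fenestrations** — radial pores through the endothelium (60 nm diameter
  in normal vessels, 240 nm in tumour vessels; channel length 400 nm, a
  typical endothelial thickness). A wall-proximal particle whose radius is
  strictly smaller than the pore radius, and whose wall projection lies
  within the clearance `pore radius - particle radius` of a pore centre,
  enters the channel and performs a sub-stepped Brownian walk
  (`dt_pore = dt/1000`) until it either crosses the outer end
  (translocated, absorbing) or returns to the lumen.

At capillary scale the Reynolds number is ~1e-3, so the inertial term of
the momentum equation is negligible: the solver computes quasi-static
incompressible Stokes flow. Because all cells move at a common speed in a
periodic domain, the flow is steady in the cell co-moving frame: it is
solved once per configuration and translated to the current cell positions
each step, rather than re-solved on a
cadence (the `flow_resolve_every` key is retained for configurations that
break this symmetry).

## The flow solver

The axisymmetric meridional plane `(r, z)` is triangulated on a structured
grid and discretised with equal-order P1/P1 elements plus
Galerkin/least-squares pressure stabilisation: for linear elements the
element momentum residual reduces to `grad(p) - f`, so the stabilisation
adds `tau (grad p, grad q)` to the continuity equation with the matching
consistency term `tau (f, grad q)` on the right-hand side
(`tau = alpha h^2 / mu`, `alpha = 0.01`). With the consistency term the
method commits no mass error for fully developed flow, and cross-section
flux is conserved to well under 1% even in heavily obstructed jittered
cell arrangements. An experimental pressure-gradient-projection variant
(`stab_pgp`) that subtracts the nodal projection of `grad(p)` from the
stabilised residual is available but off by default.

Red blood cells enter the discrete problem as nodal Dirichlet constraints:
every node inside a cell carries the cell's rigid-body velocity. This
immersed treatment (rather than boundary-fitted remeshing) keeps the mesh
structured, which gives O(1) point location during particle advection.
Two consequences are handled explicitly:

* fluid films between neighbouring cells thinner than ~2 mesh layers
  cannot be resolved; their nodes are constrained to co-move with the
  cells (the lubrication limit), and jittered placements keep a 500 nm
  minimum face gap;
* pressure is pinned to zero at nodes buried so deep inside a cell that
  every incident element is fully velocity-constrained (the pressure there
  is physically meaningless and otherwise ill-conditioned).

Axial periodicity identifies the `z = L` nodes with their `z = 0`
partners, and the pressure drop is applied as the equivalent constant
axial body force `dp / L`; with that splitting the periodic pressure
fluctuation is the unknown and the stabilisation term injects no spurious
mass in the unobstructed vessel (the acellular average dispersion factor
evaluates to ~1e-9). The driving pressure is calibrated so the
Poiseuille centreline speed at the run viscosity is 5500 um/s, a
physiological capillary centreline speed.

The cell speed solve exploits Stokes linearity: the net axial reaction
force on the constrained cell nodes is affine in the driven cell speed, so
two solves and a linear interpolation find the force-free speed exactly
(a bracketing iteration would converge to the same zero). The resulting
speed lies between the mean and centreline flow speeds, and approaches the
centreline speed as the cell radius shrinks.

### Validation oracles

* acellular flow vs the closed-form Poiseuille parabola (max relative
  error < 1% at `nr = 40`, halving under mesh refinement);
* gap flow past a nearly lumen-filling cell at zero pressure drop vs the
  annular Couette log profile (< 5%);
* trapped fluid between wide cells at zero pressure drop co-moves with the
  cells (the high-haematocrit "cellular phase").

## Viscosity, haematocrit and cell geometry

The effective suspension viscosity follows
`mu(H) = mu_p (1 + 2.5 H + 7.35 H^2)` — the Einstein coefficient at first
order with a quadratic crowding term, chosen as a minimal smooth
superlinear relation; an exponential alternative is selectable. Published
instrument-calibrated viscosity-haematocrit tables vary between sources,
so this relation is a documented stand-in; the haematocrit sweep's
qualitative behaviour does not depend on its precise coefficients.

The parachute cell shape is a shell bounded by two congruent paraboloidal
caps offset by a constant axial thickness: concave upstream face, convex
downstream cap. The constant offset makes the revolved volume exactly
`pi a^2 t`, so the thickness follows from the cell volume (94 um^3
default) and the cap depth (1200 nm default) is a free shape parameter.
The post-deformation effective radius defaults to 2900 nm, a plausible
value for a parachute-deformed cell in an 8 um vessel; it is configurable
because reported post-deformation radii vary. Particle diffusion coefficients use the
plasma viscosity (particles diffuse in plasma between cells), while the
flow solve uses the effective suspension viscosity.

## Dispersion statistics

The dispersion factor of a mesh element is `DF = V_R / v_z` with
`V_R = sqrt(v_x^2 + v_y^2)`; the average dispersion factor (ADF) is the
unweighted mean over fluid elements (cell interiors excluded). One
numerical exclusion applies, counted and reported: elements with `|v_z|`
below 1% of the field maximum, where the ratio is numerically meaningless
(nearly stagnant pockets between cells). An acellular vessel gives
ADF = 0 to solver precision; cellular vessels give ADF of order 0.01-0.03
at the default resolution, rising from zero through the capillary
haematocrit range, peaking near 20%, and declining again once the cells
close ranks and the flow splits into a cellular and a cell-free phase.
Sweep summaries aggregate replicate placements by the median.

## Brownian machinery

Gaussian displacements use the polar (modified) Box-Muller transformation
implemented in compiled code against R's RNG, so `set.seed()` makes entire
runs bit-reproducible (a single global stream; run-level determinism is
the tested contract). The default time step `dt = 1e-4 s` resolves the
advective scale (0.55 um per step at the centreline); the pore sub-step
`dt_pore = 1e-7 s` keeps the per-substep Brownian excursion (~2 nm for a
20 nm particle) far below the 60 nm channel diameter. The pore walk was
validated against the gambler's-ruin first-passage law: entering at depth
`eps` of a channel of length `L` translocates with probability `eps / L`.
A particle entering a pore starts with its centre one particle radius
inside the mouth — the geometric depth at which the sphere's surface
reaches the mouth plane.

## The synthetic DLS generator

Polydisperse populations emulate Zetasizer-style size-class tables: a
lognormal distribution with stated mean diameter and polydispersity index
(`pdi = variance / mean^2`) is binned into 26 logarithmically spaced
classes over 1-1000 nm. Sampling picks a class by inverse CDF on the
class weights and a diameter within the class from a piecewise-linear
density whose endpoint values are interpolated from the neighbouring
classes' mean densities — a minimal smooth reading of "weighting by the
neighbouring classes". Weights are treated as number-weighted;
intensity-to-number conversion of raw DLS data is out of scope. What the
generator does not emulate: instrument noise, multimodal populations, and
intensity weighting — conclusions about real DLS inputs therefore rest on
the CSV import path, not on the generator.

## Default protocol and problem sizes

The defaults define a reference protocol: haematocrit 10.7% for transport
runs (physiological for capillaries), binding range 20 nm, uptake readout
at 0.5 s, fenestration density 1 pore/um^2 (a round mid-range figure;
this default gives ~1260 pores on the default vessel), force-balance traces over 0.003 s at
`dt = 1e-4 s` from the vessel centre and a wall-adjacent start. Test-suite
runs use 150-200 particles and meshes of 24 x 120 to 24 x 250 cells —
sizes chosen so the full suite runs on a laptop-class single core in
minutes while keeping Monte-Carlo error within the asserted tolerances;
the physics does not change at larger n, only the error bars shrink.

## Known limitations

* Cells are rigid, identical, axisymmetric and radially centred: no
  deformation, slipper/bullet shapes, off-axis motion, or cell-cell
  hydrodynamics beyond excluded volume.
* No glycocalyx, receptor binding, or transmural pressure-driven flow;
  hindered diffusion inside pores is not modelled (free `D` is used).
* Particle-particle interactions are ignored (dilute limit).
* The specificity score is defined as
  `specificity_ratio x tumour uptake fraction` — the minimal form
  combining specificity with delivery efficiency, since the source
  presentation of the formula is not machine-readable; the combination is
  a pluggable hook.
* The immersed staircase representation of cell boundaries makes
  near-boundary fields first-order accurate; dispersion statistics at
  high haematocrit carry visible replicate-to-replicate noise, which the
  median aggregation addresses.
* Polydispersity penalties are direction-sensitive to the shape of the
  size distribution. With the number-weighted lognormal generator at
  pdi 0.1, a 160 nm population delivers *less volume* but *more particle
  counts* through 240 nm pores than its monodisperse match: per-particle
  uptake rises steeply below the pore cut-off (entry clearance and
  diffusivity both favour small spheres), so the sub-160 nm half of the
  population outweighs its ~7% blocked tail. A count-based polydispersity
  deficit requires substantially more super-cut-off mass than this
  generator produces — instrument-style intensity-weighted distributions
  are far heavier at large sizes. The count-direction check in the
  acceptance tests is kept at its original strictness and records this
  known discrepancy by failing under the default generator.
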