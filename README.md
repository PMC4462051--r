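# capsim

Agent-based simulation of nanoparticle transport in capillary blood flow.

`capsim` is for researchers studying blood-mediated nanoparticle delivery —
how carrier size and polydispersity govern whether particles reach the
vessel wall and cross it into tissue. It simulates a single capillary
(a hollow cylinder, ~8 um diameter) containing three interacting agent
types:

* **red blood cells**: rigid axisymmetric parachute-shaped obstacles,
  radially centred, advancing at their force-free speed in the
  pressure-driven flow;
* **nanoparticles**: spheres of 10–160 nm combining laminar advection with
  Brownian motion, reflected at the wall and excluded from cell interiors;
* **fenestrations**: radial pores through the endothelium (60 nm in normal
  vessels, 240 nm in tumour vessels) through which wall-proximal particles
  can translocate by a sub-stepped Brownian walk.

## The model in brief

Flow is quasi-static incompressible Stokes (capillary Reynolds number
~1e-3), solved on an axisymmetric finite-element mesh with equal-order
P1/P1 elements and Galerkin/least-squares pressure stabilisation; red
blood cells impose rigid-body velocity constraints on the nodes they
cover. Particles advance by the overdamped update

    x(t + dt) = x(t) + u(x) dt + N(0, sigma^2 I),   sigma = sqrt(2 D dt)

with `D = k_B T / (6 pi mu r)` (Stokes–Einstein) sampled by the polar
Box–Muller method. Derived statistics include the dispersion factor
`DF = sqrt(v_x^2 + v_y^2) / v_z` and its element average (ADF), the
fraction of particles within the 20 nm binding range of the wall, mean
squared displacement and its laminar/Brownian decomposition, percentage
uptake through fenestrations, the specificity ratio
(tumour uptake / normal uptake) and specificity score
(ratio x tumour uptake fraction), delivered particle volume, and
Holm–Sidak-adjusted multiple t-tests.

## Worked example

Ten seconds of wall-clock time, one capillary at 10.7% haematocrit with
tumour-sized (240 nm) fenestrations and 150 monodisperse 100 nm particles,
followed for 0.5 s:

```r
library(capsim)
cfg <- simulation_config(
  particles     = list(n = 150, population = list(type = "mono", diameter = 100)),
  fenestrations = list(density = 1, diameter = 240),
  time          = list(total = 0.5, record_every = 0),
  mesh          = list(nr = 24, nz = 120),
  seed          = 11)
res <- simulate_capillary(cfg)
res
#> <capsim_result> 150 particles after 5000 steps (0.5 s): 129 free, 0 in pore, 21 translocated
res$summary$pct_translocated
#> [1] 14
res$summary$rbc_velocity
#> [1] 3316.139
```

About 14% of the 100 nm particles cross 240 nm tumour fenestrations within
0.5 s, while the same population in a normal vessel (60 nm pores) delivers
exactly nothing — 100 nm spheres cannot fit a 60 nm pore — which is the
size-selectivity underlying passive tumour targeting (the EPR effect).
The red blood cells move at ~3300 um/s, between the mean and centreline
plasma speeds.

The experiment drivers reproduce whole studies:

```r
# dispersion vs haematocrit (acellular to whole blood)
sweep <- run_experiment_haematocrit_sweep(
  simulation_config(mesh = list(nr = 24, nz = 250)),
  H_values = c(0, 0.05, 0.107, 0.15, 0.20, 0.25, 0.30, 0.38, 0.45),
  replicates = 3)
round(aggregate(adf ~ H, sweep, median), 4)
#>       H    adf
#> 1 0.000 0.0000
#> 2 0.050 0.0068
#> 3 0.107 0.0226
#> 4 0.150 0.0274
#> 5 0.200 0.0330
#> 6 0.250 0.0227
#> 7 0.300 0.0141
#> 8 0.380 0.0051
#> 9 0.450 0.0021
```

The average dispersion factor is zero in the acellular vessel (Poiseuille
flow is parallel to the wall), rises through the physiological capillary
haematocrit range as flow manoeuvres around the cells, peaks near 20%,
and falls again at high haematocrit as the flow separates into a cellular
and a cell-free phase.

A thin command-line front end with the same verbs lives at
`inst/cli/capsim.R` (`run`, `sweep-haematocrit`, `fenestration`,
`force-balance`, `validate`).

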