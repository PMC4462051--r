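Package: capsim
Title: Agent-Based Simulation of Nanoparticle Transport in Capillary Blood Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the transport of nanoparticles in single capillaries
    using an agent-based approach. Quasi-static incompressible flow is solved
    on an axisymmetric finite-element mesh with Galerkin/least-squares
    pressure stabilisation, with red blood cells represented as rigid
    axisymmetric parachute-shaped obstacles moving at their force-free speed.
    Nanoparticles advance under combined laminar advection and Brownian
    displacements (polar Box-Muller sampling of Stokes-Einstein diffusion),
    with specular wall reflection and red-blood-cell excluded volume.
    Vessel-wall fenestrations are modelled as radial pores through which
    particles translocate by a sub-stepped Brownian walk, capturing the
    size selectivity of the enhanced permeability and retention effect.
    Includes polydisperse size-population sampling from dynamic light
    scattering style size-class tables, dispersion and binding-range
    statistics, mean squared displacement decomposition, specificity
    ratio/score, delivered-volume accounting and Holm-Sidak multiple-testing
    adjustment, plus experiment drivers for haematocrit sweeps and
    fenestration uptake studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
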