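#' Simulation configuration
#'
#' Aggregates every tunable of a capillary run: vessel geometry, fluid
#' properties, haematocrit, red-blood-cell shape, nanoparticle population,
#' fenestration spec, time stepping, toggles and seed. All defaults follow
#' the reference protocol documented in the methods vignette (4000 nm
#' vessel radius, 10.7% haematocrit, dt = 1e-4 s, 20 nm binding range,
#' 60/240 nm pores, 0.5 s uptake readout).
#'
#' @param geometry List of [vessel_geometry()] arguments.
#' @param fluid List of [fluid_properties()] arguments.
#' @param haematocrit Haematocrit fraction in [0, 0.45]. Default 0.107.
#' @param rbc List: `effective_radius` (nm), `cell_volume` (um^3),
#'   `cap_depth` (nm), `spacing_rule`, `jitter_frac`.
#' @param particles List: `n` (count) and `population` — one of
#'   `list(type = "mono", diameter = )`,
#'   `list(type = "dls_file", file = )`, or
#'   `list(type = "synthetic", mean_diameter = , pdi = )`.
#' @param fenestrations List: `density` (pores/um^2), `diameter` (nm),
#'   `capture` (nm). `density = 0` disables pores.
#' @param time List: `dt` (s), `dt_pore` (s), `total` (s),
#'   `flow_resolve_every` (steps), `record_every` (steps; 0 = no
#'   trajectory).
#' @param mesh List: `nr`, `nz` cells.
#' @param toggles List: `brownian_on`, `laminar_on`.
#' @param seed Integer RNG seed recorded in every output.
#' @param output List: `dir` or `NULL`.
#' @return A validated object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = list(), fluid = list(),
                              haematocrit = 0.107, rbc = list(),
                              particles = list(), fenestrations = list(),
                              time = list(), mesh = list(),
                              toggles = list(), seed = 1L,
                              output = list(dir = NULL)) {
  merge_defaults <- function(user, defaults, where) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(unknown, collapse = ", ")))
    utils::modifyList(defaults, user, keep.null = TRUE)
  }
  geometry <- merge_defaults(geometry,
                             list(radius = 4000, length = 50000,
                                  periodic_axial = TRUE,
                                  wall_thickness = 400), "geometry")
  fluid <- merge_defaults(fluid,
                          list(density = 1000, plasma_viscosity = 1.2e-3,
                               temperature = 310, pressure_drop = NULL,
                               v_center_target = 5500), "fluid")
  rbc <- merge_defaults(rbc,
                        list(effective_radius = 2900, cell_volume = 94,
                             cap_depth = 1200, spacing_rule = "uniform",
                             jitter_frac = 0.8), "rbc")
  particles <- merge_defaults(particles,
                              list(n = 200,
                                   population = list(type = "mono",
                                                     diameter = 100)),
                              "particles")
  fenestrations <- merge_defaults(fenestrations,
                                  list(density = 0, diameter = 60,
                                       capture = 20), "fenestrations")
  time <- merge_defaults(time,
                         list(dt = 1e-4, dt_pore = 1e-7, total = 0.003,
                              flow_resolve_every = 10, record_every = 1),
                         "time")
  mesh <- merge_defaults(mesh, list(nr = 40, nz = 200), "mesh")
  toggles <- merge_defaults(toggles,
                            list(brownian_on = TRUE, laminar_on = TRUE),
                            "toggles")
  output <- merge_defaults(output, list(dir = NULL), "output")
  problems <- character(0)
  if (haematocrit < 0 || haematocrit > 0.45)
    problems <- c(problems, "haematocrit must lie in [0, 0.45]")
  if (time$total < time$dt)
    problems <- c(problems, "total time must be >= dt")
  if (time$dt_pore > time$dt)
    problems <- c(problems, "dt_pore must be <= dt")
  if (particles$n < 0)
    problems <- c(problems, "particle count must be >= 0")
  if (!particles$population$type %in% c("mono", "dls_file", "synthetic"))
    problems <- c(problems, "population type must be mono/dls_file/synthetic")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  structure(list(geometry = geometry, fluid = fluid,
                 haematocrit = haematocrit, rbc = rbc,
                 particles = particles, fenestrations = fenestrations,
                 time = time, mesh = mesh, toggles = toggles,
                 seed = as.integer(seed), output = output),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> H = %.1f%%, %d particles (%s), ",
                     "%g s at dt %g s, seed %d\n"),
              100 * x$haematocrit, x$particles$n, x$particles$population$type,
              x$time$total, x$time$dt, x$seed))
  invisible(x)
}

#' Load a simulation configuration from YAML
#'
#' Unknown keys at any level are rejected (fail-fast), with every violation
#' listed.
#'
#' @param file Path to a YAML configuration file.
#' @return A [simulation_config()].
#' @export
load_config <- function(file) {
  raw <- yaml::read_yaml(file)
  top <- c("geometry", "fluid", "haematocrit", "rbc", "particles",
           "fenestrations", "time", "mesh", "toggles", "seed", "output")
  unknown <- setdiff(names(raw), top)
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  args <- raw[intersect(top, names(raw))]
  do.call(simulation_config, args)
}

#' Write a simulation configuration to YAML
#' @param config A [simulation_config()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file, precision = 15)
  invisible(file)
}

#' Resolve a size population spec into a size distribution
#' @noRd
population_distribution <- function(pop) {
  switch(pop$type,
         mono = monodisperse(pop$diameter),
         dls_file = parse_dls_table(pop$file),
         synthetic = synthetic_dls(pop$mean_diameter, pop$pdi))
}
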