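#' Haematocrit sweep of dispersion and wall-proximity metrics
#'
#' For each haematocrit (and replicate seed) the flow problem is solved with
#' jittered RBC placement and the average dispersion factor computed; when
#' `particles > 0` a particle simulation additionally yields the binding
#' range fraction, mean radial position and mean particle speeds (whole
#' vessel and the wall-proximal subset).
#'
#' @param config A [simulation_config()] providing everything but the
#'   haematocrit.
#' @param H_values Haematocrit fractions in [0, 0.45].
#' @param replicates Replicate placements/seeds per haematocrit. Default 3.
#' @param particles Particle count for the per-H transport run; 0 (default)
#'   computes flow-only metrics.
#' @return Data.frame with one row per (H, replicate): `H`, `replicate`,
#'   `adf`, `rbc_velocity`, and (particle runs only) `pct_binding_range`,
#'   `mean_radial_position`, `mean_speed`, `mean_speed_wall`.
#' @export
run_experiment_haematocrit_sweep <- function(config, H_values,
                                             replicates = 3,
                                             particles = 0) {
  if (any(H_values < 0 | H_values > 0.45))
    stop("haematocrit values must lie in [0, 0.45]")
  geom <- do.call(vessel_geometry, config$geometry)
  fluid <- do.call(fluid_properties, config$fluid)
  rows <- list()
  for (H in H_values) {
    for (rep_i in seq_len(replicates)) {
      seed <- config$seed + 1000L * (rep_i - 1L) +
        as.integer(round(1e4 * H))
      set.seed(seed)
      mu_eff <- effective_viscosity(H, fluid$plasma_viscosity)
      n_rbc <- haematocrit_to_rbc_count(H, geom, config$rbc$cell_volume)
      rbcs <- place_rbcs(n_rbc, geom,
                         spacing_rule = if (n_rbc > 0 && replicates > 1)
                           "jittered" else config$rbc$spacing_rule,
                         jitter_frac = config$rbc$jitter_frac,
                         effective_radius = config$rbc$effective_radius,
                         cell_volume = config$rbc$cell_volume,
                         cap_depth = config$rbc$cap_depth)
      mesh <- build_mesh(geom, config$mesh$nr, config$mesh$nz)
      if (length(rbcs)) {
        ff <- rbc_force_free_velocity(mesh, fluid, rbcs, mu = mu_eff)
        field <- ff$field
      } else {
        field <- solve_flow(mesh, fluid, mu = mu_eff)
      }
      adf <- average_dispersion_factor(field, rbcs)
      row <- data.frame(H = H, replicate = rep_i, adf = adf$adf,
                        rbc_velocity = field$rbc_velocity,
                        pct_binding_range = NA_real_,
                        mean_radial_position = NA_real_,
                        mean_speed = NA_real_, mean_speed_wall = NA_real_)
      if (particles > 0) {
        cfg_h <- config
        cfg_h$haematocrit <- H
        cfg_h$particles$n <- particles
        cfg_h$seed <- seed
        res <- simulate_capillary(cfg_h, field = field, rbcs = rbcs)
        free_now <- res$status == "free"
        pos <- res$position[free_now, , drop = FALSE]
        rad <- res$diameter[free_now] / 2
        row$pct_binding_range <- res$summary$pct_binding_range
        row$mean_radial_position <- res$summary$mean_radial_position
        shift <- field$rbc_velocity * res$n_steps * config$time$dt * 1e3
        u <- interpolate_velocity(field, pos, shift)
        spd <- sqrt(rowSums(u^2))
        row$mean_speed <- mean(spd)
        gap <- geom$radius - sqrt(pos[, 1]^2 + pos[, 2]^2) - rad
        if (any(gap <= 20)) row$mean_speed_wall <- mean(spd[gap <= 20])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Fenestration uptake experiment across populations and pore sizes
#'
#' Runs the 0.5 s uptake protocol for each size population against normal
#' (60 nm) and tumour (240 nm) fenestrations, then derives the specificity
#' ratio and score per population.
#'
#' @param config A [simulation_config()]; its fenestration density and
#'   capture distance are reused, the diameter is swept.
#' @param populations List of [size_distribution()] objects (or population
#'   spec lists as in [simulation_config()]).
#' @param pore_diameters Pore diameters in nm. Default `c(60, 240)`.
#' @param seeds Integer vector of replicate seeds; default the config seed.
#' @return Data.frame with one row per (population, pore size, seed):
#'   uptake percentage, delivered volume, mean translocated and luminal
#'   diameter; specificity ratio/score attached per population x seed via
#'   the paired 60/240 runs (`NA` when either leg is missing).
#' @export
run_experiment_fenestration <- function(config, populations,
                                        pore_diameters = c(60, 240),
                                        seeds = NULL) {
  if (is.null(seeds)) seeds <- config$seed
  rows <- list()
  # flow solve is shared across populations and pore sizes per seed
  for (seed in seeds) {
    cfg0 <- config
    cfg0$seed <- as.integer(seed)
    set.seed(cfg0$seed)
    geom <- do.call(vessel_geometry, cfg0$geometry)
    fluid <- do.call(fluid_properties, cfg0$fluid)
    mu_eff <- effective_viscosity(cfg0$haematocrit, fluid$plasma_viscosity)
    n_rbc <- haematocrit_to_rbc_count(cfg0$haematocrit, geom,
                                      cfg0$rbc$cell_volume)
    rbcs <- place_rbcs(n_rbc, geom, spacing_rule = cfg0$rbc$spacing_rule,
                       jitter_frac = cfg0$rbc$jitter_frac,
                       effective_radius = cfg0$rbc$effective_radius,
                       cell_volume = cfg0$rbc$cell_volume,
                       cap_depth = cfg0$rbc$cap_depth)
    mesh <- build_mesh(geom, cfg0$mesh$nr, cfg0$mesh$nz)
    field <- if (length(rbcs))
      rbc_force_free_velocity(mesh, fluid, rbcs, mu = mu_eff)$field
    else solve_flow(mesh, fluid, mu = mu_eff)
    for (pi_ in seq_along(populations)) {
      pop <- populations[[pi_]]
      label <- if (inherits(pop, "size_distribution")) pop$label
               else paste(unlist(pop), collapse = "/")
      for (dia in pore_diameters) {
        cfg <- cfg0
        cfg$fenestrations$density <- config$fenestrations$density
        cfg$fenestrations$diameter <- dia
        if (inherits(pop, "size_distribution")) {
          cfg$particles$population <- list(type = "mono", diameter = NA)
          res <- simulate_with_distribution(cfg, pop, field, rbcs)
        } else {
          cfg$particles$population <- pop
          res <- simulate_capillary(cfg, field = field, rbcs = rbcs)
        }
        s <- res$summary
        rows[[length(rows) + 1L]] <-
          data.frame(population = label, pore_diameter = dia, seed = seed,
                     pct_uptake = s$pct_translocated,
                     delivered_volume = s$delivered_volume,
                     mean_diameter_translocated =
                       s$mean_diameter_translocated,
                     mean_diameter_luminal = s$mean_diameter_luminal)
      }
    }
  }
  tab <- do.call(rbind, rows)
  # attach specificity per population x seed from the 60/240 pairing
  tab$specificity_ratio <- NA_real_
  tab$specificity_score <- NA_real_
  if (all(c(60, 240) %in% pore_diameters)) {
    for (lb in unique(tab$population)) {
      for (sd in unique(tab$seed)) {
        sel <- tab$population == lb & tab$seed == sd
        u60 <- tab$pct_uptake[sel & tab$pore_diameter == 60]
        u240 <- tab$pct_uptake[sel & tab$pore_diameter == 240]
        if (length(u60) == 1L && length(u240) == 1L) {
          tab$specificity_ratio[sel] <- specificity_ratio(u240, u60)
          tab$specificity_score[sel] <- specificity_score(u240, u60)
        }
      }
    }
  }
  tab
}

# Run simulate_capillary with an explicit size_distribution object (the
# config population spec only carries serialisable descriptions).
simulate_with_distribution <- function(config, dist, field = NULL,
                                       rbcs = NULL) {
  force(dist)
  cfg <- config
  if (dist$monodisperse) {
    cfg$particles$population <- list(type = "mono",
                                     diameter = dist$class_edges[1])
    return(simulate_capillary(cfg, field, rbcs))
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_dls_table(dist, tmp)
  cfg$particles$population <- list(type = "dls_file", file = tmp)
  simulate_capillary(cfg, field, rbcs)
}

#' Laminar/Brownian force-balance decomposition
#'
#' Reruns the same seeded trajectory with (a) both displacement components,
#' (b) laminar only, (c) Brownian only, for particles started at the vessel
#' centre and wall-adjacent, and reports the MSD series of each run
#' (default protocol: 100 nm particles, 0.003 s at dt = 1e-4 s).
#'
#' @param config A [simulation_config()]; `total` and `dt` default to the
#'   trace protocol. The vessel is run acellular: the decomposition
#'   isolates laminar vs Brownian displacement of the tracer, and
#'   collisions with passing cells would contaminate the Brownian-only
#'   leg.
#' @param start `"centre"` or `"wall"` start position.
#' @param n_particles Ensemble size. Default 25.
#' @return List of three data.frames (`both`, `laminar_only`,
#'   `brownian_only`) from [msd_series()], plus the trajectories.
#' @export
run_experiment_force_balance <- function(config, start = c("centre", "wall"),
                                         n_particles = 25) {
  start <- match.arg(start)
  geom <- do.call(vessel_geometry, config$geometry)
  r_part <- config$particles$population$diameter / 2
  rho0 <- if (start == "centre") 0 else geom$radius - r_part - 20
  modes <- list(both = c(TRUE, TRUE), laminar_only = c(TRUE, FALSE),
                brownian_only = c(FALSE, TRUE))
  out <- list()
  trajs <- list()
  field <- NULL; rbcs <- NULL
  for (m in names(modes)) {
    cfg <- config
    cfg$haematocrit <- 0
    cfg$particles$n <- n_particles
    cfg$toggles$laminar_on <- modes[[m]][1]
    cfg$toggles$brownian_on <- modes[[m]][2]
    cfg$time$record_every <- 1
    cfg$fenestrations$density <- 0
    res <- simulate_force_balance_run(cfg, rho0, field, rbcs)
    field <- res$field; rbcs <- res$rbcs
    out[[m]] <- msd_series(res$trajectory, res$times)
    trajs[[m]] <- res$trajectory
  }
  c(out, list(trajectories = trajs, start = start))
}

# One force-balance run with particles pinned to a fixed start radius.
simulate_force_balance_run <- function(config, rho0, field = NULL,
                                       rbcs = NULL) {
  set.seed(config$seed)
  geom <- do.call(vessel_geometry, config$geometry)
  fluid <- do.call(fluid_properties, config$fluid)
  mu_eff <- effective_viscosity(config$haematocrit, fluid$plasma_viscosity)
  if (is.null(rbcs)) {
    n_rbc <- haematocrit_to_rbc_count(config$haematocrit, geom,
                                      config$rbc$cell_volume)
    rbcs <- place_rbcs(n_rbc, geom, spacing_rule = config$rbc$spacing_rule,
                       jitter_frac = config$rbc$jitter_frac,
                       effective_radius = config$rbc$effective_radius,
                       cell_volume = config$rbc$cell_volume,
                       cap_depth = config$rbc$cap_depth)
  }
  if (is.null(field)) {
    mesh <- build_mesh(geom, config$mesh$nr, config$mesh$nz)
    field <- if (length(rbcs))
      rbc_force_free_velocity(mesh, fluid, rbcs, mu = mu_eff)$field
    else solve_flow(mesh, fluid, mu = mu_eff)
  }
  n <- config$particles$n
  r_part <- config$particles$population$diameter / 2
  # spread along z in a cell-free window, fixed start radius
  z0 <- seq(0.05, 0.95, length.out = n) * geom$length
  th0 <- rep(0, n)
  position <- cbind(rho0 * cos(th0), rho0 * sin(th0), z0)
  # keep clear of RBC interiors at start
  position <- resolve_rbc_overlap(position, r_part, rbcs, geom)
  sigma <- brownian_sigma(
    diffusion_coefficient(fluid$temperature, fluid$plasma_viscosity,
                          r_part), config$time$dt)
  n_steps <- max(1L, as.integer(round(config$time$total / config$time$dt)))
  traj <- array(NA_real_, c(n_steps + 1L, n, 3L))
  traj[1, , ] <- position
  for (s in seq_len(n_steps)) {
    shift <- field$rbc_velocity * s * config$time$dt * 1e3
    position <- advance_particles(position, r_part, sigma, field,
                                  config$time$dt, geom, rbcs, shift,
                                  laminar_on = config$toggles$laminar_on,
                                  brownian_on = config$toggles$brownian_on)
    traj[s + 1L, , ] <- position
  }
  list(trajectory = traj, times = seq(0, by = config$time$dt,
                                      length.out = n_steps + 1L),
       field = field, rbcs = rbcs)
}

#' MSD decomposition into laminar and Brownian contributions
#'
#' Convenience wrapper around [run_experiment_force_balance()] returning
#' the three MSD series (total, laminar-only, Brownian-only) evaluated at
#' the final time, with the relative shares.
#'
#' @inheritParams run_experiment_force_balance
#' @return List with the three [msd_series()] data.frames and
#'   `share_laminar`, `share_brownian` (fractions of the summed final
#'   component MSDs).
#' @export
msd_decomposition <- function(config, start = "centre", n_particles = 25) {
  fb <- run_experiment_force_balance(config, start, n_particles)
  lam <- utils::tail(fb$laminar_only$msd, 1)
  bro <- utils::tail(fb$brownian_only$msd, 1)
  tot <- lam + bro
  c(fb[c("both", "laminar_only", "brownian_only")],
    list(share_laminar = lam / tot, share_brownian = bro / tot))
}
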