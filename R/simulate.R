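#' Run a capillary nanoparticle transport simulation
#'
#' The agent main loop with synchronous state updates. Per step: (1) red
#' blood cells advance at their force-free speed (with periodic wrap); (2)
#' the flow field — solved once, since it is steady in the RBC co-moving
#' frame — is translated to the current RBC positions; (3) each free
#' nanoparticle advects, takes a Brownian displacement, reflects at the
#' wall and is pushed out of RBCs; (4) wall-proximal particles test pore
#' entry; (5) in-pore particles run the sub-stepped pore walk; (6) metrics
#' accumulate.
#'
#' @param config A [simulation_config()].
#' @param field Optional pre-solved [solve_flow()] field matching the
#'   configuration (reused across runs in experiment drivers).
#' @param rbcs Optional RBC list matching `field`.
#' @return An object of class `capsim_result`: particle `position` (n x 3
#'   nm, axially unwrapped), `diameter`, `status`, `ledger` (event
#'   data.frame), `trajectory` (time x particle x 3 array or `NULL`),
#'   `times`, the `field`, `rbcs`, `fen`, `summary` (uptake and dispersion
#'   metrics) and the `config`.
#' @export
#' @examples
#' cfg <- simulation_config(haematocrit = 0, particles = list(n = 10),
#'                          time = list(total = 5e-4), mesh = list(nr = 8, nz = 16))
#' res <- simulate_capillary(cfg)
#' res$summary$pct_translocated
simulate_capillary <- function(config, field = NULL, rbcs = NULL) {
  set.seed(config$seed)
  geom <- do.call(vessel_geometry, config$geometry)
  fluid <- do.call(fluid_properties, config$fluid)
  H <- config$haematocrit
  mu_eff <- effective_viscosity(H, fluid$plasma_viscosity)

  if (is.null(rbcs)) {
    n_rbc <- haematocrit_to_rbc_count(H, geom, config$rbc$cell_volume)
    rbcs <- place_rbcs(n_rbc, geom,
                       spacing_rule = config$rbc$spacing_rule,
                       jitter_frac = config$rbc$jitter_frac,
                       effective_radius = config$rbc$effective_radius,
                       cell_volume = config$rbc$cell_volume,
                       cap_depth = config$rbc$cap_depth)
  }
  if (is.null(field)) {
    mesh <- build_mesh(geom, config$mesh$nr, config$mesh$nz)
    if (length(rbcs)) {
      ff <- rbc_force_free_velocity(mesh, fluid, rbcs, mu = mu_eff)
      field <- ff$field
    } else {
      field <- solve_flow(mesh, fluid, mu = mu_eff)
    }
  }
  v_rbc <- field$rbc_velocity                       # um/s

  fen <- NULL
  if (config$fenestrations$density > 0)
    fen <- place_fenestrations(geom, config$fenestrations$density,
                               config$fenestrations$diameter)

  # --- particle population ------------------------------------------------
  n <- config$particles$n
  dist <- population_distribution(config$particles$population)
  diameter <- if (n > 0) sample_sizes(dist, n) else numeric(0)
  radius <- diameter / 2
  D_c <- if (n > 0)
    diffusion_coefficient(fluid$temperature, fluid$plasma_viscosity, radius)
  else numeric(0)
  sigma <- if (n > 0) brownian_sigma(D_c, config$time$dt) else numeric(0)

  position <- matrix(0, n, 3L)
  if (n > 0) {
    # uniform in the accessible cross-section and length, outside RBCs
    todo <- seq_len(n)
    guard <- 0L
    while (length(todo)) {
      guard <- guard + 1L
      if (guard > 1000L) stop("could not place particles outside RBCs")
      m <- length(todo)
      R_acc <- geom$radius - radius[todo]
      rho <- R_acc * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      zz <- stats::runif(m, 0, geom$length)
      position[todo, ] <- cbind(rho * cos(th), rho * sin(th), zz)
      bad <- rep(FALSE, m)
      for (cell in rbcs)
        bad <- bad | rbc_contains(cell, rho, zz, pad = radius[todo])
      todo <- todo[bad]
    }
  }

  status <- rep("free", n)
  pore_id <- rep(NA_integer_, n)
  pore_state <- matrix(0, n, 3L)                     # depth, lateral a, b
  ledger <- list()
  n_steps <- max(1L, as.integer(round(config$time$total / config$time$dt)))
  record_every <- config$time$record_every
  n_rec <- if (record_every > 0) n_steps %/% record_every + 1L else 0L
  traj <- if (n_rec > 0 && n > 0) array(NA_real_, c(n_rec, n, 3L)) else NULL
  times <- if (n_rec > 0) seq(0, by = config$time$dt * max(record_every, 1L),
                              length.out = n_rec) else numeric(0)
  if (!is.null(traj)) traj[1, , ] <- position
  rec <- 1L

  dt <- config$time$dt
  brow <- config$toggles$brownian_on
  lam <- config$toggles$laminar_on
  for (s in seq_len(n_steps)) {
    t_now <- s * dt
    shift <- v_rbc * t_now * 1e3                    # um/s * s -> nm
    free_idx <- which(status == "free")
    if (length(free_idx)) {
      p_free <- position[free_idx, , drop = FALSE]
      p_free <- advance_particles(p_free, radius[free_idx],
                                  sigma[free_idx], field, dt, geom,
                                  rbcs = rbcs, shift = shift,
                                  laminar_on = lam, brownian_on = brow)
      position[free_idx, ] <- p_free
      if (!is.null(fen)) {
        ent <- try_enter_pore(p_free, radius[free_idx], fen,
                              capture = config$fenestrations$capture)
        hit <- which(!is.na(ent))
        for (k in hit) {
          i <- free_idx[k]
          status[i] <- "in_pore"
          pore_id[i] <- ent[k]
          # centre starts one particle radius inside the channel mouth
          pore_state[i, ] <- c(radius[i], 0, 0)
          ledger[[length(ledger) + 1L]] <-
            data.frame(time = t_now, particle = i, pore = ent[k],
                       event = "enter")
        }
      }
    }
    inp <- which(status == "in_pore")
    if (length(inp) && !is.null(fen)) {
      st <- pore_state[inp, , drop = FALSE]
      pw <- pore_walk(st, radius[inp], if (brow) D_c[inp] else 0 * D_c[inp],
                      fen, dt, config$time$dt_pore)
      pore_state[inp, ] <- pw$pore_state
      for (k in seq_along(inp)) {
        i <- inp[k]
        if (pw$outcome[k] == "translocated") {
          status[i] <- "translocated"
          ledger[[length(ledger) + 1L]] <-
            data.frame(time = t_now, particle = i, pore = pore_id[i],
                       event = "translocate")
        } else if (pw$outcome[k] == "returned") {
          status[i] <- "free"
          pr <- fen$pores[fen$pores$id == pore_id[i], ]
          rho_back <- geom$radius - radius[i]
          th <- pr$theta
          position[i, ] <- c(rho_back * cos(th), rho_back * sin(th), pr$z)
          ledger[[length(ledger) + 1L]] <-
            data.frame(time = t_now, particle = i, pore = pore_id[i],
                       event = "return")
          pore_id[i] <- NA_integer_
        }
      }
    }
    if (!is.null(traj) && record_every > 0 && s %% record_every == 0L) {
      rec <- rec + 1L
      if (rec <= n_rec) traj[rec, , ] <- position
    }
  }

  ledger <- if (length(ledger)) do.call(rbind, ledger)
            else data.frame(time = numeric(0), particle = integer(0),
                            pore = integer(0), event = character(0))
  summary <- if (n > 0) {
    us <- uptake_summary(ledger, diameter, status)
    free_now <- status == "free"
    c(us,
      list(pct_binding_range = if (any(free_now))
             fraction_within_binding_range(
               position[free_now, , drop = FALSE], radius[free_now], geom)
           else NA_real_,
           mean_radial_position = if (any(free_now))
             mean_radial_position(position[free_now, , drop = FALSE])
           else NA_real_,
           rbc_velocity = v_rbc,
           haematocrit_achieved = achieved_haematocrit(rbcs, geom)))
  } else {
    list(pct_translocated = NA_real_, rbc_velocity = v_rbc,
         haematocrit_achieved = achieved_haematocrit(rbcs, geom))
  }

  res <- structure(list(position = position, diameter = diameter,
                        status = status, ledger = ledger,
                        trajectory = traj, times = times,
                        field = field, rbcs = rbcs, fen = fen,
                        summary = summary, config = config,
                        n_steps = n_steps),
                   class = "capsim_result")
  if (!is.null(config$output$dir)) write_outputs(res, config$output$dir)
  res
}

#' @export
print.capsim_result <- function(x, ...) {
  cat(sprintf(paste0("<capsim_result> %d particles after %d steps ",
                     "(%g s): %d free, %d in pore, %d translocated\n"),
              length(x$diameter), x$n_steps,
              x$n_steps * x$config$time$dt,
              sum(x$status == "free"), sum(x$status == "in_pore"),
              sum(x$status == "translocated")))
  invisible(x)
}
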