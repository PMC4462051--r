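#' Place fenestrations on the vessel wall
#'
#' Fenestrations are narrow pores perpendicular to the vessel wall. They are
#' placed uniformly at random on the cylindrical surface, rejecting
#' placements whose surface distance to an existing pore is below one pore
#' diameter (non-overlap).
#'
#' @param geom A [vessel_geometry()].
#' @param density Pores per um^2 of wall area (>= 0). Default 1.
#' @param diameter Pore diameter in nm; 60 (normal vessel) or 240 (tumour
#'   vessel) by convention. Default 60.
#' @param max_attempts Rejection-sampling attempt multiplier. Default 50.
#' @return An object of class `fenestration_set`: data.frame `pores` with
#'   columns `id`, `theta` (rad), `z` (nm), `diameter` (nm), plus
#'   `channel_length` (nm, the endothelial wall thickness) and `geom`.
#' @export
place_fenestrations <- function(geom, density = 1, diameter = 60,
                                max_attempts = 50) {
  if (density < 0) stop("density must be >= 0")
  if (!diameter %in% c(60, 240))
    message("note: pore diameter ", diameter,
            " nm is outside the 60/240 nm normal/tumour convention")
  wall_area_um2 <- 2 * pi * (geom$radius * 1e-3) * (geom$length * 1e-3)
  n_target <- stats::rpois(1, density * wall_area_um2)
  theta <- numeric(0); zz <- numeric(0)
  attempts <- 0L
  R <- geom$radius; L <- geom$length
  while (length(theta) < n_target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts * max(n_target, 1L))
      stop(sprintf(paste0("could not place %d non-overlapping pores after ",
                          "%d attempts (density too high)"),
                   n_target, attempts - 1L))
    th <- stats::runif(1, 0, 2 * pi)
    z <- stats::runif(1, 0, L)
    if (length(theta)) {
      dth <- abs(theta - th)
      dth <- pmin(dth, 2 * pi - dth)
      dz <- abs(zz - z)
      if (geom$periodic_axial) dz <- pmin(dz, L - dz)
      if (min(sqrt((R * dth)^2 + dz^2)) <= diameter) next
    }
    theta <- c(theta, th); zz <- c(zz, z)
  }
  structure(list(pores = data.frame(id = seq_along(theta), theta = theta,
                                    z = zz,
                                    diameter = rep(diameter,
                                                   length(theta))),
                 channel_length = geom$wall_thickness,
                 geom = geom),
            class = "fenestration_set")
}

#' @export
print.fenestration_set <- function(x, ...) {
  cat(sprintf("<fenestration_set> %d pores of %g nm, channel %g nm\n",
              nrow(x$pores), x$pores$diameter[1], x$channel_length))
  invisible(x)
}

#' Test pore entry for wall-proximal particles
#'
#' A particle can enter a pore iff (i) its radius is strictly smaller than
#' the pore radius (hard-sphere exclusion), (ii) its surface is within the
#' capture distance of the wall, and (iii) its wall projection lies within
#' `pore radius - particle radius` of the pore centre (strict clearance).
#'
#' @param position n x 3 particle centres (nm), lab frame.
#' @param radius Particle radii (nm, scalar or length n).
#' @param fen A [place_fenestrations()] result.
#' @param capture Capture distance from particle surface to wall in nm
#'   (shared with the binding range). Default 20.
#' @return Integer vector of length n: the pore id entered, or `NA` if none.
#' @export
try_enter_pore <- function(position, radius, fen, capture = 20) {
  geom <- fen$geom
  n <- nrow(position)
  if (length(radius) == 1L) radius <- rep(radius, n)
  out <- rep(NA_integer_, n)
  if (nrow(fen$pores) == 0L) return(out)
  rho <- sqrt(position[, 1]^2 + position[, 2]^2)
  gap <- geom$radius - rho - radius
  cand <- which(gap <= capture & radius < fen$pores$diameter[1] / 2)
  if (!length(cand)) return(out)
  R <- geom$radius; L <- geom$length
  th_p <- atan2(position[cand, 2], position[cand, 1])
  z_p <- position[cand, 3] %% L
  pore_r <- fen$pores$diameter / 2
  for (k in seq_along(cand)) {
    clear <- pore_r - radius[cand[k]]
    dth <- abs(fen$pores$theta - th_p[k])
    dth <- pmin(dth, 2 * pi - dth)
    dz <- abs(fen$pores$z - z_p[k])
    if (geom$periodic_axial) dz <- pmin(dz, L - dz)
    d <- sqrt((R * dth)^2 + dz^2)
    ok <- which(d < clear)
    if (length(ok)) out[cand[k]] <- fen$pores$id[ok[which.min(d[ok])]]
  }
  out
}

#' Brownian walk of in-pore particles over one vessel time step
#'
#' Particles inside a fenestration channel advance by a sub-stepped Brownian
#' walk (time step `dt_pore`, much shorter than the vessel step because of
#' the narrow geometry). The channel is a cylinder of length equal to the
#' endothelial wall thickness; lateral excursions reflect at the channel
#' wall accounting for the particle radius. Crossing the outer end
#' translocates the particle (absorbing); re-crossing the inner mouth
#' returns it to the lumen.
#'
#' @param pore_state n x 3 matrix: depth along the channel axis, and two
#'   lateral coordinates (nm).
#' @param radius Particle radii (nm, length n).
#' @param D_c Diffusion coefficients (m^2/s, length n).
#' @param fen A [place_fenestrations()] result.
#' @param dt Vessel time step (s).
#' @param dt_pore Pore sub-step (s); `dt / dt_pore` sub-steps are taken.
#' @return List with `outcome` (character: `in_transit`, `translocated`,
#'   `returned`) and the updated `pore_state`.
#' @export
pore_walk <- function(pore_state, radius, D_c, fen, dt, dt_pore = dt / 1000) {
  n <- nrow(pore_state)
  if (n == 0L)
    return(list(outcome = character(0), pore_state = pore_state))
  pore_r <- fen$pores$diameter[1] / 2
  if (any(radius >= pore_r))
    stop("particle radius >= pore radius inside a pore (blocked at entry)")
  sigma <- brownian_sigma(D_c, dt_pore)
  rho_max <- pore_r - radius
  n_sub <- max(1L, as.integer(round(dt / dt_pore)))
  code <- .pore_walk_cpp(pore_state, sigma, rho_max, fen$channel_length,
                         n_sub)
  list(outcome = c("in_transit", "translocated", "returned")[code + 1L],
       pore_state = pore_state)
}

#' Summarise fenestration uptake
#'
#' @param ledger Data.frame of events with columns `time`, `particle`,
#'   `pore`, `event` (`enter`, `return`, `translocate`).
#' @param diameters Diameters (nm) of the whole particle population.
#' @param status Character vector of current particle status
#'   (`free`, `in_pore`, `translocated`).
#' @return List with `pct_translocated`, `pct_in_pore`,
#'   `mean_diameter_translocated`, `mean_diameter_luminal`,
#'   `delivered_volume` (nm^3) and the per-status `counts`.
#' @export
uptake_summary <- function(ledger, diameters, status) {
  n <- length(diameters)
  if (n == 0L) stop("empty particle population")
  stopifnot(length(status) == n)
  trans <- status == "translocated"
  inp <- status == "in_pore"
  lum <- status == "free"
  list(pct_translocated = 100 * sum(trans) / n,
       pct_in_pore = 100 * sum(inp) / n,
       mean_diameter_translocated = if (any(trans)) mean(diameters[trans])
                                    else NA_real_,
       mean_diameter_luminal = if (any(lum)) mean(diameters[lum])
                               else NA_real_,
       delivered_volume = delivered_volume(diameters[trans]),
       counts = c(free = sum(lum), in_pore = sum(inp),
                  translocated = sum(trans)))
}
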