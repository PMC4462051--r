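#' Stokes-Einstein diffusion coefficient
#'
#' `D_c = k_B T / (6 pi mu r)` for a sphere of radius `r` in a fluid of
#' viscosity `mu` at temperature `T`.
#'
#' @param temperature Absolute temperature in K.
#' @param mu Dynamic viscosity in Pa.s.
#' @param radius Particle radius in nm; vectorised.
#' @return Diffusion coefficient in m^2/s.
#' @export
#' @examples
#' diffusion_coefficient(310, 1.2e-3, 50)
diffusion_coefficient <- function(temperature, mu, radius) {
  if (temperature <= 0 || mu <= 0) stop("temperature and mu must be > 0")
  if (any(radius <= 0)) stop("radius must be > 0")
  kB <- 1.380649e-23
  kB * temperature / (6 * pi * mu * radius * 1e-9)
}

#' Per-axis Brownian step standard deviation
#'
#' `sigma = sqrt(2 D_c dt)` converted to nm; the per-axis Gaussian width of
#' an overdamped Brownian displacement over one time step.
#'
#' @param D_c Diffusion coefficient in m^2/s (>= 0); vectorised.
#' @param dt Time step in s (> 0).
#' @return Standard deviation in nm.
#' @export
brownian_sigma <- function(D_c, dt) {
  if (any(D_c < 0)) stop("D_c must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  sqrt(2 * D_c * dt) * 1e9
}

#' Brownian stepper
#'
#' Bundles the diffusion coefficient, time step and per-axis step standard
#' deviation for one particle size. Reproducibility is governed by R's
#' global RNG (`set.seed()`); the Gaussian draws use the polar (modified)
#' Box-Muller transformation.
#'
#' @param D_c Diffusion coefficient (m^2/s).
#' @param dt Time step (s).
#' @return An object of class `brownian_stepper` with fields `D_c`, `dt`
#'   and `sigma` (nm).
#' @export
brownian_stepper <- function(D_c, dt) {
  structure(list(D_c = D_c, dt = dt, sigma = brownian_sigma(D_c, dt)),
            class = "brownian_stepper")
}

#' Draw Brownian displacement vectors
#'
#' Zero-mean Gaussian displacements with per-axis standard deviation
#' `sigma`, generated by the polar (modified) Box-Muller method in all three
#' axes.
#'
#' @param stepper A [brownian_stepper()], or a numeric sigma in nm.
#' @param n Number of 3-vectors to draw. Default 1.
#' @return n x 3 matrix of displacements in nm.
#' @export
brownian_step <- function(stepper, n = 1) {
  sigma <- if (inherits(stepper, "brownian_stepper")) stepper$sigma
           else as.numeric(stepper)
  matrix(.polar_gaussians(3L * n, sigma), ncol = 3L)
}

#' Specular reflection at the vessel wall
#'
#' The wall is reflective for nanoparticle collisions: if the particle
#' surface overshoots the wall (`rho + r > R`), the centre is mirrored about
#' the accessible cylinder `rho = R - r`; the axial coordinate is unchanged
#' and interior points are returned as-is. Large overshoots are folded
#' iteratively.
#'
#' @param position n x 3 matrix (or length-3 vector) of centre positions (nm).
#' @param radius Particle radius in nm (scalar or length n).
#' @param geom A [vessel_geometry()].
#' @param max_iter Maximum mirror folds before giving up. Default 10.
#' @return Reflected positions, same shape as input.
#' @export
reflect_at_wall <- function(position, radius, geom, max_iter = 10) {
  vec_in <- is.null(dim(position))
  if (vec_in) position <- matrix(position, ncol = 3L)
  R_acc <- geom$radius - radius
  if (any(R_acc <= 0)) stop("particle radius exceeds vessel radius")
  rho <- sqrt(position[, 1]^2 + position[, 2]^2)
  over <- rho > R_acc
  it <- 0L
  while (any(over)) {
    it <- it + 1L
    if (it > max_iter)
      stop("wall reflection did not converge (overshoot too large)")
    rho_new <- 2 * (if (length(R_acc) > 1L) R_acc[over] else R_acc) - rho[over]
    # a fold past the axis is folded back to positive radius
    rho_new <- abs(rho_new)
    scale <- ifelse(rho[over] > 0, rho_new / rho[over], 0)
    position[over, 1] <- position[over, 1] * scale
    position[over, 2] <- position[over, 2] * scale
    rho[over] <- rho_new
    over <- rho > R_acc
  }
  if (vec_in) position[1, ] else position
}

#' Push particles out of red blood cells
#'
#' Nanoparticles and red blood cells cannot occupy the same space. A
#' particle sphere intersecting a cell is projected back along the local
#' outward surface normal of the revolved parachute profile to tangential
#' contact. For an axisymmetric surface the 3D distance equals the 2D
#' distance from (rho, z) to the meridional profile polyline.
#'
#' @param position n x 3 matrix of particle centres (nm), in the RBC frame.
#' @param radius Particle radius in nm (scalar or length n).
#' @param rbcs List of [rbc_agent()].
#' @param geom A [vessel_geometry()] (for wall clamping after push-out).
#' @param n_profile Profile sampling density for the projection. Default 48.
#' @return Corrected n x 3 position matrix.
#' @export
resolve_rbc_overlap <- function(position, radius, rbcs, geom,
                                n_profile = 48) {
  if (length(rbcs) == 0L) return(position)
  vec_in <- is.null(dim(position))
  if (vec_in) position <- matrix(position, ncol = 3L)
  if (length(radius) == 1L) radius <- rep(radius, nrow(position))
  rho <- sqrt(position[, 1]^2 + position[, 2]^2)
  z <- position[, 3]
  L <- geom$length
  for (cell in rbcs) {
    cells <- list(cell)
    if (geom$periodic_axial) {
      lo <- cell; lo$z_center <- cell$z_center - L
      hi <- cell; hi$z_center <- cell$z_center + L
      cells <- c(cells, list(lo, hi))
    }
    for (cc in cells) {
      hit <- which(rbc_contains(cc, rho, z, pad = radius))
      if (!length(hit)) next
      prof <- rbc_boundary_profile(cc, n_profile)
      for (k in hit) {
        q <- closest_point_on_polyline(rho[k], z[k], prof$r, prof$z)
        drho <- rho[k] - q[1]; dz <- z[k] - q[2]
        d <- sqrt(drho^2 + dz^2)
        inside <- rbc_contains(cc, rho[k], z[k])
        if (inside) { drho <- -drho; dz <- -dz }
        if (d < 1e-12) { drho <- 1; dz <- 0; d <- 1 }
        # place centre at distance `radius` outside the surface
        rho_new <- q[1] + drho / d * radius[k]
        z_new <- q[2] + dz / d * radius[k]
        rho_new <- max(rho_new, 0)
        if (rho[k] > 0) {
          sc <- rho_new / rho[k]
          position[k, 1] <- position[k, 1] * sc
          position[k, 2] <- position[k, 2] * sc
        } else {
          position[k, 1] <- rho_new
        }
        position[k, 3] <- z_new
        rho[k] <- rho_new
        z[k] <- z_new
      }
    }
  }
  # never leave a particle through the wall
  position <- reflect_at_wall(position, radius, geom)
  if (vec_in) position[1, ] else position
}

# Closest point on a polyline to (x0, y0); returns c(x, y). Segments lying
# entirely on the axis (r = 0) close the revolved profile but are not part
# of the physical surface and are skipped.
closest_point_on_polyline <- function(x0, y0, px, py) {
  ax <- px[-length(px)]; ay <- py[-length(py)]
  bx <- px[-1L]; by <- py[-1L]
  keep <- pmax(ax, bx) > 1e-9
  ax <- ax[keep]; ay <- ay[keep]; bx <- bx[keep]; by <- by[keep]
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- ((x0 - ax) * vx + (y0 - ay) * vy) / pmax(L2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * vx; qy <- ay + t * vy
  d2 <- (x0 - qx)^2 + (y0 - qy)^2
  k <- which.min(d2)
  c(qx[k], qy[k])
}

#' Signed distance from meridional points to an RBC surface
#'
#' Positive outside the cell, negative inside.
#'
#' @param rbc An [rbc_agent()].
#' @param rho,z Coordinates in nm (vectorised).
#' @param n_profile Profile sampling density. Default 96.
#' @return Numeric vector of signed distances in nm.
#' @export
rbc_signed_distance <- function(rbc, rho, z, n_profile = 96) {
  prof <- rbc_boundary_profile(rbc, n_profile)
  out <- numeric(length(rho))
  for (k in seq_along(rho)) {
    q <- closest_point_on_polyline(rho[k], z[k], prof$r, prof$z)
    d <- sqrt((rho[k] - q[1])^2 + (z[k] - q[2])^2)
    out[k] <- if (rbc_contains(rbc, rho[k], z[k])) -d else d
  }
  out
}

#' Advance free particles by one time step
#'
#' Overdamped update: the laminar displacement `u(x) dt` (from the flow
#' field) and the Brownian displacement (polar Box-Muller draws scaled by
#' `sigma`) add vectorially to the total displacement, after which wall
#' reflection and RBC excluded volume are applied. `laminar_on` /
#' `brownian_on` toggles support the force-decomposition analysis.
#'
#' @param position n x 3 matrix of particle centres (nm).
#' @param radius Particle radii in nm (scalar or length n).
#' @param sigma Per-axis Brownian standard deviations in nm (scalar or
#'   length n).
#' @param field A [solve_flow()] result, or `NULL` for no flow.
#' @param dt Time step (s).
#' @param geom A [vessel_geometry()].
#' @param rbcs List of [rbc_agent()] in the same frame as the field.
#' @param shift Axial lab-to-field frame shift in nm (see
#'   [interpolate_velocity()]).
#' @param laminar_on,brownian_on Toggles for the two displacement
#'   components.
#' @return Updated n x 3 position matrix (z wrapped if periodic).
#' @export
advance_particles <- function(position, radius, sigma, field, dt, geom,
                              rbcs = list(), shift = 0,
                              laminar_on = TRUE, brownian_on = TRUE) {
  n <- nrow(position)
  disp <- matrix(0, n, 3L)
  if (laminar_on && !is.null(field)) {
    u <- interpolate_velocity(field, position, shift)  # um/s
    disp <- disp + u * dt * 1e3                        # um/s * s -> nm
  }
  if (brownian_on) {
    if (length(sigma) == 1L) {
      disp <- disp + matrix(.polar_gaussians(3L * n, sigma), ncol = 3L)
    } else {
      g <- matrix(.polar_gaussians(3L * n, 1), ncol = 3L)
      disp <- disp + g * sigma
    }
  }
  pos <- position + disp
  dimnames(pos) <- NULL
  pos <- reflect_at_wall(pos, radius, geom)
  if (length(rbcs)) {
    # excluded volume acts in the RBC frame; the axial coordinate stays
    # unwrapped (for MSD) so only the frame-local correction is applied back
    zf <- pos[, 3] - shift
    if (geom$periodic_axial) zf <- zf %% geom$length
    posf <- cbind(pos[, 1], pos[, 2], zf)
    posf <- resolve_rbc_overlap(posf, radius, rbcs, geom)
    pos[, 1] <- posf[, 1]
    pos[, 2] <- posf[, 2]
    pos[, 3] <- pos[, 3] + (posf[, 3] - zf)
  }
  pos
}
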