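#' Vessel geometry
#'
#' Defines the cylindrical capillary domain. The capillary is treated as a
#' hollow cylinder with no-slip walls; all lengths are stored in nanometres.
#'
#' @param radius Vessel (lumen) radius in nm. Default 4000 nm, i.e. an 8 um
#'   diameter capillary.
#' @param length Vessel length in nm. Default 50000 nm.
#' @param periodic_axial Logical; treat the axial direction as periodic
#'   (particles and red blood cells wrap around). Default `TRUE`.
#' @param wall_thickness Endothelial wall thickness in nm; this is the channel
#'   length of fenestration pores. Default 400 nm.
#'
#' @return An object of class `vessel_geometry`.
#' @export
#' @examples
#' geom <- vessel_geometry()
#' geom$radius
vessel_geometry <- function(radius = 4000, length = 50000,
                            periodic_axial = TRUE, wall_thickness = 400) {
  stopifnot(is.numeric(radius), length(radius) == 1L,
            is.numeric(length), is.numeric(wall_thickness))
  if (radius <= 0) stop("vessel radius must be > 0")
  if (length <= 0) stop("vessel length must be > 0")
  if (wall_thickness <= 0) stop("wall_thickness must be > 0")
  structure(list(radius = radius, length = length,
                 periodic_axial = isTRUE(periodic_axial),
                 wall_thickness = wall_thickness),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> radius %g nm, length %g nm, wall %g nm, %s\n",
              x$radius, x$length, x$wall_thickness,
              if (x$periodic_axial) "periodic axial" else "open ends"))
  invisible(x)
}

#' Vessel volume in nm^3
#' @param geom A [vessel_geometry()].
#' @return Volume in nm^3.
#' @export
vessel_volume <- function(geom) pi * geom$radius^2 * geom$length

#' Red blood cell agent
#'
#' An axisymmetric, radially centred, parachute-shaped rigid obstacle.  The
#' parachute is approximated as a shell bounded by two congruent paraboloidal
#' caps: a convex cap on the downstream (+z) face and a concave (indented)
#' upstream face offset by a constant axial thickness.  With a constant axial
#' offset the revolved volume is exactly `pi * effective_radius^2 * thickness`,
#' so the thickness is derived from the requested cell volume and the cap
#' depth is a free shape parameter.
#'
#' @param z_center Axial position of the cell centre (nm).
#' @param velocity_z Axial speed (um/s); must be >= 0.
#' @param effective_radius Maximum radial extent after deformation (nm).
#'   Default 2900 nm (literature-style post-deformation radius; configurable).
#' @param cell_volume Cell volume in um^3. Default 94 um^3.
#' @param cap_depth Axial depth of the paraboloidal cap (nm). Default 1200 nm.
#' @param geom Optional [vessel_geometry()] used to validate confinement.
#'
#' @return An object of class `rbc_agent` with fields `z_center`,
#'   `velocity_z`, `effective_radius`, `cell_volume`, `cap_depth`,
#'   `thickness` (derived, nm) and `axial_extent` (cap_depth + thickness, nm).
#' @export
rbc_agent <- function(z_center = 0, velocity_z = 0, effective_radius = 2900,
                      cell_volume = 94, cap_depth = 1200, geom = NULL) {
  if (effective_radius <= 0) stop("effective_radius must be > 0")
  if (cell_volume <= 0) stop("cell_volume must be > 0")
  if (velocity_z < 0) stop("velocity_z must be >= 0")
  if (cap_depth < 0) stop("cap_depth must be >= 0")
  if (!is.null(geom) && effective_radius >= geom$radius)
    stop("RBC effective_radius must be strictly smaller than the vessel radius")
  vol_nm3 <- cell_volume * 1e9           # um^3 -> nm^3
  thickness <- vol_nm3 / (pi * effective_radius^2)
  structure(list(z_center = z_center, velocity_z = velocity_z,
                 effective_radius = effective_radius,
                 cell_volume = cell_volume, cap_depth = cap_depth,
                 thickness = thickness,
                 axial_extent = cap_depth + thickness),
            class = "rbc_agent")
}

#' Haematocrit
#'
#' Volume fraction of the vessel occupied by red blood cells. Capillary
#' haematocrit is typically 10-12%; whole blood is ~45%.
#'
#' @param fraction Dimensionless volume fraction in [0, 0.45].
#' @return A validated numeric scalar of class `haematocrit`.
#' @export
haematocrit <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction))
    stop("haematocrit must be a single number")
  if (fraction < 0 || fraction > 0.45)
    stop("haematocrit must lie in [0, 0.45] (acellular to whole blood)")
  structure(fraction, class = "haematocrit")
}

#' Number of red blood cells for a target haematocrit
#'
#' @param H Haematocrit fraction (or [haematocrit()] object).
#' @param geom A [vessel_geometry()].
#' @param cell_volume RBC volume in um^3. Default 94.
#' @return Integer cell count, `round(H * vessel volume / cell volume)`.
#' @export
#' @examples
#' haematocrit_to_rbc_count(0.107, vessel_geometry())
haematocrit_to_rbc_count <- function(H, geom, cell_volume = 94) {
  H <- as.numeric(H)
  if (H < 0) stop("haematocrit must be >= 0")
  if (cell_volume <= 0) stop("cell_volume must be > 0")
  vol_um3 <- vessel_volume(geom) / 1e9   # nm^3 -> um^3
  as.integer(round(H * vol_um3 / cell_volume))
}

#' Place red blood cells along the vessel axis
#'
#' Cells are radially centred and distributed along the axis. The `"uniform"`
#' rule places cell `i` at `(2 i - 1) / (2 count)` of the vessel length; the
#' `"jittered"` rule perturbs each uniform centre by a uniform random offset
#' within the free slack so that cells never overlap (used for replicate
#' haematocrit sweeps).
#'
#' @param count Number of cells.
#' @param geom A [vessel_geometry()].
#' @param spacing_rule `"uniform"` or `"jittered"`.
#' @param jitter_frac Fraction of the per-cell slack used for jitter
#'   (0 to 1). Default 0.8.
#' @param ... Passed to [rbc_agent()] (e.g. `effective_radius`,
#'   `cell_volume`, `cap_depth`).
#' @return List of [rbc_agent()] objects (empty list for `count = 0`).
#' @export
place_rbcs <- function(count, geom, spacing_rule = c("uniform", "jittered"),
                       jitter_frac = 0.8, ...) {
  spacing_rule <- match.arg(spacing_rule)
  count <- as.integer(count)
  if (count < 0) stop("count must be >= 0")
  if (count == 0L) return(list())
  template <- rbc_agent(geom = geom, ...)
  # successive parachutes nest (the convex cap fits the next cell's
  # concavity), so the minimum centre spacing is the shell thickness
  footprint <- template$thickness * 1.02
  spacing <- geom$length / count
  if (footprint >= spacing) {
    max_feasible <- floor(geom$length / footprint)
    stop(sprintf(paste0("cannot fit %d RBCs of footprint %.0f nm in a ",
                        "%.0f nm vessel; maximum feasible count is %d"),
                 count, footprint, geom$length, max(0L, max_feasible)))
  }
  centers <- (2 * seq_len(count) - 1) / (2 * count) * geom$length
  if (spacing_rule == "jittered") {
    # keep a 500 nm minimum face-to-face gap so neighbouring shells never
    # pinch the fluid film between them shut
    slack <- max((spacing - template$thickness - 500) / 2, 0)
    centers <- centers + stats::runif(count, -jitter_frac * slack,
                                      jitter_frac * slack)
  }
  lapply(centers, function(zc) rbc_agent(z_center = zc, geom = geom, ...))
}

#' Parachute boundary profile of a red blood cell
#'
#' Returns a closed polyline of (r, z) points tracing the axisymmetric cell
#' boundary in the meridional half-plane: concave upstream face, rim edge,
#' convex downstream cap.  Revolving the polyline about the axis recovers the
#' cell volume.
#'
#' @param rbc An [rbc_agent()].
#' @param n_points Number of sample points per face (>= 8).
#' @return A data.frame with columns `r` and `z` (nm); first row equals the
#'   last row.
#' @export
rbc_boundary_profile <- function(rbc, n_points = 32) {
  if (n_points < 8) stop("n_points must be >= 8")
  a <- rbc$effective_radius
  d <- rbc$cap_depth
  t <- rbc$thickness
  zc <- rbc$z_center
  # downstream (+z) convex face: z = zc + t/2 + d*(1 - (r/a)^2) - d
  # parameterise so the cell centre is mid-thickness at the rim
  z_down <- function(r) zc + t / 2 + d * (1 - (r / a)^2)
  z_up   <- function(r) z_down(r) - t
  r_seq <- seq(0, a, length.out = n_points)
  up   <- data.frame(r = r_seq, z = z_up(r_seq))
  down <- data.frame(r = rev(r_seq), z = z_down(rev(r_seq)))
  prof <- rbind(up,
                data.frame(r = a, z = z_down(a)),  # rim edge
                down,
                up[1, , drop = FALSE])             # close along the axis
  rownames(prof) <- NULL
  prof
}

#' Axial faces of the parachute shell at radius r
#'
#' Internal helper: lower (upstream) and upper (downstream) z of the cell at
#' radius `r` relative to the cell centre frame. Vectorised over `r`.
#' @noRd
rbc_faces <- function(rbc, r) {
  a <- rbc$effective_radius
  zd <- rbc$z_center + rbc$thickness / 2 + rbc$cap_depth * (1 - (r / a)^2)
  list(z_up = zd - rbc$thickness, z_down = zd)
}

#' Test whether meridional points lie inside a red blood cell
#'
#' @param rbc An [rbc_agent()].
#' @param r,z Vectors of radial/axial coordinates (nm), in the same frame as
#'   `rbc$z_center`.
#' @param pad Optional padding (nm) inflating the cell (e.g. a particle
#'   radius for excluded-volume tests). Default 0.
#' @return Logical vector.
#' @export
rbc_contains <- function(rbc, r, z, pad = 0) {
  a <- rbc$effective_radius + pad
  inside_r <- r <= a
  # evaluate faces with the unpadded shape but padded bounds
  f <- rbc_faces(rbc, pmin(r, rbc$effective_radius))
  inside_r & z >= (f$z_up - pad) & z <= (f$z_down + pad)
}

#' Achieved haematocrit of a cell arrangement
#' @param rbcs List of [rbc_agent()].
#' @param geom A [vessel_geometry()].
#' @return Volume fraction actually occupied.
#' @export
achieved_haematocrit <- function(rbcs, geom) {
  if (length(rbcs) == 0L) return(0)
  sum(vapply(rbcs, function(x) x$cell_volume, numeric(1))) * 1e9 /
    vessel_volume(geom)
}
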