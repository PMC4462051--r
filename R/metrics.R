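#' Radial velocity magnitude
#'
#' `V_R = sqrt(v_x^2 + v_y^2)`: the speed component directed towards (or
#' away from) the vessel wall.
#'
#' @param v_x,v_y Velocity components in um/s; vectorised.
#' @return Radial speed in um/s (>= 0).
#' @export
radial_velocity <- function(v_x, v_y) sqrt(v_x^2 + v_y^2)

#' Dispersion factor
#'
#' `DF = V_R / v_z`: the ratio of radial to longitudinal flow speed. A
#' dispersion factor of 0 means flow parallel to the vessel wall (no
#' dispersion); larger values mean trajectories angled towards/away from
#' the wall.
#'
#' @param V_R Radial speed (um/s).
#' @param v_z Longitudinal speed (um/s).
#' @return DF, with `NaN` where `v_z = 0` and `V_R > 0` (undefined
#'   elements, to be excluded and counted by the caller) and 0 where both
#'   vanish.
#' @export
dispersion_factor <- function(V_R, v_z) {
  out <- V_R / v_z
  out[V_R == 0] <- 0
  out[v_z == 0 & V_R > 0] <- NaN
  out
}

#' Average dispersion factor over the fluid elements
#'
#' Unweighted mean of the element-centroid dispersion factor over fluid
#' elements. Elements whose centroid lies inside a red blood cell are
#' excluded (they carry no fluid), as are elements with `v_z = 0` and
#' nonzero radial speed (undefined DF; counted, not zero-filled).
#'
#' @param field A [solve_flow()] result.
#' @param rbcs List of [rbc_agent()] defining the exclusion mask; defaults
#'   to the RBCs stored in the field.
#' @param vz_tol Relative tolerance below which an element's longitudinal
#'   speed counts as vanishing: elements with
#'   `|v_z| <= vz_tol * max |v_z|` are flagged undefined (the ratio
#'   `V_R / v_z` is numerically meaningless in nearly stagnant
#'   recirculation pockets between cells). Default 0.01.
#' @return List with `adf`, the element count `n_elements` used, and
#'   `n_undefined` excluded for vanishing longitudinal speed.
#' @export
average_dispersion_factor <- function(field, rbcs = field$rbcs,
                                      vz_tol = 0.01) {
  mesh <- field$mesh
  cent <- element_centroids(mesh)
  el <- mesh$elements
  vr_c <- (field$v_r[el[, 1]] + field$v_r[el[, 2]] + field$v_r[el[, 3]]) / 3
  vz_c <- (field$v_z[el[, 1]] + field$v_z[el[, 2]] + field$v_z[el[, 3]]) / 3
  fluid <- rep(TRUE, nrow(el))
  if (length(rbcs)) {
    L <- mesh$geom$length
    for (cell in rbcs) {
      fluid <- fluid & !rbc_contains(cell, cent[, 1], cent[, 2])
      if (mesh$geom$periodic_axial) {
        lo <- cell; lo$z_center <- cell$z_center - L
        hi <- cell; hi$z_center <- cell$z_center + L
        fluid <- fluid & !rbc_contains(lo, cent[, 1], cent[, 2]) &
          !rbc_contains(hi, cent[, 1], cent[, 2])
      }
    }
  }
  if (!any(fluid)) stop("all elements are masked by RBCs")
  vz_f <- vz_c[fluid]
  df <- dispersion_factor(abs(vr_c[fluid]), vz_f)
  undef <- !is.finite(df) | abs(vz_f) <= vz_tol * max(abs(vz_f))
  list(adf = mean(abs(df[!undef])), n_elements = sum(!undef),
       n_undefined = sum(undef))
}

#' Mean squared displacement
#'
#' `MSD(t) = |x(t) - x(0)|^2`, averaged over particles when `positions` is
#' an ensemble.
#'
#' @param positions_t n x 3 positions at time t (nm); a vector for one
#'   particle.
#' @param positions_0 Matching positions at time 0.
#' @return Ensemble-mean MSD in nm^2.
#' @export
msd <- function(positions_t, positions_0) {
  if (is.null(dim(positions_t))) positions_t <- matrix(positions_t, ncol = 3)
  if (is.null(dim(positions_0))) positions_0 <- matrix(positions_0, ncol = 3)
  if (!all(dim(positions_t) == dim(positions_0)))
    stop("mismatched position sets")
  mean(rowSums((positions_t - positions_0)^2))
}

#' MSD series from a trajectory array
#'
#' @param traj Array (time, particle, 3) of positions in nm, first slice
#'   the initial condition.
#' @param times Vector of times (s) matching the first dimension.
#' @return Data.frame with columns `time` and `msd` (nm^2); `msd[1] = 0`.
#' @export
msd_series <- function(traj, times) {
  stopifnot(length(dim(traj)) == 3L, dim(traj)[1] == length(times))
  x0 <- traj[1, , , drop = FALSE]
  data.frame(time = times,
             msd = vapply(seq_along(times), function(i) {
               msd(matrix(traj[i, , ], ncol = 3), matrix(x0[1, , ], ncol = 3))
             }, numeric(1)))
}

#' Fraction of particles within binding range of the wall
#'
#' A particle counts when the gap from its proximal surface to the vessel
#' wall, `R - rho - r`, is at most the binding range (20 nm by default).
#'
#' @param position n x 3 particle centres (nm).
#' @param radius Particle radii (nm, scalar or length n).
#' @param geom A [vessel_geometry()].
#' @param range Binding range in nm. Default 20.
#' @return Percentage of the population within range.
#' @export
fraction_within_binding_range <- function(position, radius, geom,
                                          range = 20) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  if (nrow(position) == 0L) stop("empty particle population")
  rho <- sqrt(position[, 1]^2 + position[, 2]^2)
  gap <- geom$radius - rho - radius
  100 * mean(gap <= range)
}

#' Mean radial position of a particle population
#'
#' Average distance of particle centres from the vessel axis; for a
#' uniform-in-cross-section population over accessible radius `R_a` the
#' expectation is `(2/3) R_a`.
#'
#' @param position n x 3 particle centres (nm).
#' @return Mean radial position in nm.
#' @export
mean_radial_position <- function(position) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  if (nrow(position) == 0L) stop("empty particle population")
  mean(sqrt(position[, 1]^2 + position[, 2]^2))
}

#' Specificity ratio of tumour over normal delivery
#'
#' Ratio of the percentage of nanoparticles delivered across tumour-vessel
#' fenestrations to that across normal-vessel fenestrations.
#'
#' @param uptake_tumour,uptake_normal Percent uptake (>= 0).
#' @return The ratio; `Inf` when normal uptake is 0 and tumour uptake > 0;
#'   `NaN` for 0/0 (not computable).
#' @export
specificity_ratio <- function(uptake_tumour, uptake_normal) {
  if (any(uptake_tumour < 0) || any(uptake_normal < 0))
    stop("uptake percentages must be >= 0")
  ifelse(uptake_normal == 0,
         ifelse(uptake_tumour > 0, Inf, NaN),
         uptake_tumour / uptake_normal)
}

#' Specificity score
#'
#' A measure combining specificity and overall delivery efficiency:
#' `score = specificity_ratio * (uptake_tumour / 100)`, i.e. the
#' tumour/normal ratio weighted by the tumour delivery fraction. The
#' multiplicative form is the minimal combination that is monotone in both
#' components; alternative forms can be supplied via `combine`.
#'
#' @inheritParams specificity_ratio
#' @param combine Optional function `(ratio, tumour_fraction) -> score`
#'   replacing the default product.
#' @return The score (0 when tumour uptake is 0).
#' @export
specificity_score <- function(uptake_tumour, uptake_normal,
                              combine = NULL) {
  ratio <- specificity_ratio(uptake_tumour, uptake_normal)
  frac <- uptake_tumour / 100
  out <- if (is.null(combine)) ratio * frac else combine(ratio, frac)
  out[uptake_tumour == 0] <- 0
  out
}

#' Total delivered nanoparticle volume
#'
#' Cargo capacity is proportional to particle volume, so delivery is
#' quantified as the summed volume of translocated particles.
#'
#' @param translocated_diameters Diameters (nm) of translocated particles.
#' @return Total volume in nm^3 (0 for an empty list).
#' @export
delivered_volume <- function(translocated_diameters) {
  if (length(translocated_diameters) == 0L) return(0)
  sum(particle_volume(translocated_diameters))
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Step-down Sidak procedure: with p-values sorted ascending,
#' `adjusted_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforced monotone
#' non-decreasing and mapped back to the input order. Hypotheses are
#' rejected while the adjusted p-value is at most `alpha`.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @param alpha Significance level. Default 0.05.
#' @return List with `adjusted` (same order as input) and logical `reject`.
#' @export
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))
holm_sidak_adjust <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  # step-down rejection: reject in sorted order while adjusted <= alpha
  rej_sorted <- cumprod(adj <= alpha) == 1
  reject <- logical(m)
  reject[o] <- rej_sorted
  list(adjusted = out, reject = reject)
}

#' Two-sample t-tests on replicate simulations with Holm-Sidak correction
#'
#' Thin utility applying Welch t-tests to each row pair of two replicate
#' matrices and adjusting the p-values by the Holm-Sidak method.
#'
#' @param a,b Matrices (conditions x replicates) of a metric.
#' @param alpha Significance level. Default 0.05.
#' @return Data.frame with `p`, `adjusted`, `reject` per condition (row).
#' @export
replicate_t_tests <- function(a, b, alpha = 0.05) {
  stopifnot(nrow(a) == nrow(b))
  p <- vapply(seq_len(nrow(a)), function(i) {
    stats::t.test(a[i, ], b[i, ])$p.value
  }, numeric(1))
  hs <- holm_sidak_adjust(p, alpha)
  data.frame(p = p, adjusted = hs$adjusted, reject = hs$reject)
}
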