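#' Fluid properties of blood plasma
#'
#' @param density Fluid density in kg/m^3. Default 1000.
#' @param plasma_viscosity Plasma (acellular) dynamic viscosity in Pa.s.
#'   Default 1.2e-3.
#' @param temperature Absolute temperature in K. Default 310 (body).
#' @param pressure_drop Pressure drop in Pa over the vessel length, or `NULL`
#'   to calibrate it so the equivalent unobstructed (Poiseuille) flow at the
#'   run viscosity reaches `v_center_target` on the centreline.
#' @param v_center_target Centreline speed target in um/s used when
#'   `pressure_drop` is `NULL`. Default 5500.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, plasma_viscosity = 1.2e-3,
                             temperature = 310, pressure_drop = NULL,
                             v_center_target = 5500) {
  if (density <= 0 || plasma_viscosity <= 0 || temperature <= 0)
    stop("density, plasma_viscosity and temperature must be > 0")
  if (!is.null(pressure_drop) && pressure_drop <= 0)
    stop("pressure_drop must be > 0")
  structure(list(density = density, plasma_viscosity = plasma_viscosity,
                 temperature = temperature, pressure_drop = pressure_drop,
                 v_center_target = v_center_target),
            class = "fluid_properties")
}

#' Effective blood viscosity at a given haematocrit
#'
#' Smooth superlinear suspension-viscosity relation capturing the non-linear
#' rise of blood viscosity with haematocrit. Default polynomial form
#' `mu_p * (1 + 2.5 H + 7.35 H^2)` (Einstein coefficient at first order);
#' an exponential alternative `mu_p * exp(2.5 H / (1 - 0.61 H))` is
#' selectable.
#'
#' @param H Haematocrit fraction in [0, 0.45].
#' @param mu_p Plasma viscosity in Pa.s.
#' @param relation `"polynomial"` (default) or `"exponential"`.
#' @return Effective dynamic viscosity in Pa.s.
#' @export
#' @examples
#' effective_viscosity(0.45, 1.2e-3)
effective_viscosity <- function(H, mu_p,
                                relation = c("polynomial", "exponential")) {
  relation <- match.arg(relation)
  H <- as.numeric(H)
  if (any(H < 0 | H >= 1)) stop("haematocrit must lie in [0, 1)")
  if (mu_p <= 0) stop("plasma viscosity must be > 0")
  switch(relation,
         polynomial = mu_p * (1 + 2.5 * H + 7.35 * H^2),
         exponential = mu_p * exp(2.5 * H / (1 - 0.61 * H)))
}

#' Reynolds number
#'
#' Ratio of inertial to viscous forces, `Re = rho * v * D_H / mu`. Capillary
#' flow sits around 1e-3, far below the ~2400 transition to transient flow,
#' which justifies the quasi-static Stokes treatment.
#'
#' @param rho Density (kg/m^3).
#' @param v_mean Mean velocity (m/s).
#' @param D_H Hydraulic diameter (m).
#' @param mu Dynamic viscosity (Pa.s).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(rho, v_mean, D_H, mu) {
  if (rho <= 0 || D_H <= 0) stop("density and diameter must be > 0")
  if (mu <= 0) stop("viscosity must be > 0")
  if (v_mean < 0) stop("mean velocity must be >= 0")
  rho * v_mean * D_H / mu
}

#' Analytic Poiseuille axial velocity profile
#'
#' Closed-form pressure-driven laminar profile in a cylinder,
#' `v_z(r) = dp (R^2 - r^2) / (4 mu L)`, used as the analytic oracle for the
#' finite-element solver.
#'
#' @param geom A [vessel_geometry()].
#' @param dp Pressure drop over the vessel length (Pa).
#' @param mu Dynamic viscosity (Pa.s).
#' @param r Radial position(s) in nm, `0 <= r <= radius`.
#' @return Axial velocity in um/s.
#' @export
poiseuille_profile <- function(geom, dp, mu, r) {
  if (any(r < 0 | r > geom$radius)) stop("r must lie in [0, radius]")
  R_m <- geom$radius * 1e-9
  r_m <- r * 1e-9
  L_m <- geom$length * 1e-9
  dp * (R_m^2 - r_m^2) / (4 * mu * L_m) * 1e6   # m/s -> um/s
}

#' Pressure drop giving a target centreline Poiseuille speed
#' @param geom A [vessel_geometry()].
#' @param mu Dynamic viscosity (Pa.s).
#' @param v_center Centreline speed (um/s).
#' @return Pressure drop in Pa over the vessel length.
#' @export
calibrate_pressure_drop <- function(geom, mu, v_center = 5500) {
  R_m <- geom$radius * 1e-9
  L_m <- geom$length * 1e-9
  4 * mu * L_m * (v_center * 1e-6) / R_m^2
}

# ---------------------------------------------------------------------------
# Axisymmetric stabilised Stokes finite elements
#
# Quasi-static incompressible flow in the meridional (r, z) half-plane with
# P1/P1 equal-order elements and Galerkin/least-squares pressure
# stabilisation (for P1 the element residual reduces to the pressure
# gradient, giving the Brezzi-Pitkaranta form tau * (grad p, grad q)).
# Red blood cells are imposed as nodal Dirichlet constraints (rigid-body
# velocity) on the nodes inside each cell. Assembly is in SI units.
# ---------------------------------------------------------------------------

# Precompute per-element geometric quantities (SI metres).
flow_precompute <- function(mesh) {
  el <- mesh$elements
  xy <- mesh$nodes * 1e-9
  x1 <- xy[el[, 1], 1]; y1 <- xy[el[, 1], 2]
  x2 <- xy[el[, 2], 1]; y2 <- xy[el[, 2], 2]
  x3 <- xy[el[, 3], 1]; y3 <- xy[el[, 3], 2]
  A <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  if (any(A <= 0)) stop("mesh contains inverted or zero-area elements")
  # P1 gradients: grad(phi_i) = (b_i, c_i)
  b1 <- (y2 - y3) / (2 * A); b2 <- (y3 - y1) / (2 * A); b3 <- (y1 - y2) / (2 * A)
  c1 <- (x3 - x2) / (2 * A); c2 <- (x1 - x3) / (2 * A); c3 <- (x2 - x1) / (2 * A)
  rc <- (x1 + x2 + x3) / 3
  h2 <- pmax((x2 - x1)^2 + (y2 - y1)^2, (x3 - x2)^2 + (y3 - y2)^2,
             (x1 - x3)^2 + (y1 - y3)^2)
  list(el = el, A = A, rc = rc, h2 = h2,
       b = cbind(b1, b2, b3), c = cbind(c1, c2, c3),
       r = cbind(x1, x2, x3))
}

# Assemble the coupled sparse system (u_r, u_z, p blocks) and RHS.
#
# Driving: in periodic mode the axial periodic image nodes are identified
# with their partners and the pressure drop enters as the equivalent
# constant axial body force dp/L (the periodic pressure fluctuation is then
# the unknown); in open mode the pressure drop enters through traction
# boundary conditions at the ends.
assemble_stokes <- function(mesh, mu, dp, stab_alpha = 0.1,
                            periodic = FALSE, stab_pgp = 0,
                            pgp_mask_nodes = integer(0)) {
  pc <- flow_precompute(mesh)
  N <- nrow(mesh$nodes)
  el <- pc$el
  A <- pc$A; rc <- pc$rc
  tau <- stab_alpha * pc$h2 / mu
  # interior 3-point quadrature (barycentric permutations of (2/3,1/6,1/6))
  qb <- rbind(c(2/3, 1/6, 1/6), c(1/6, 2/3, 1/6), c(1/6, 1/6, 2/3))
  rq <- pc$r %*% t(qb)                       # element x quad point radius
  n_el <- nrow(el)
  idx <- matrix(0, n_el, 9); jdx <- matrix(0, n_el, 9)
  K_rr <- matrix(0, n_el, 9); K_zz <- matrix(0, n_el, 9)
  G_r <- matrix(0, n_el, 9); G_z <- matrix(0, n_el, 9)
  S_pp <- matrix(0, n_el, 9)
  col_of <- function(i, j) (i - 1L) * 3L + j
  for (i in 1:3) {
    for (j in 1:3) {
      cij <- col_of(i, j)
      idx[, cij] <- el[, i]
      jdx[, cij] <- el[, j]
      gg <- pc$b[, i] * pc$b[, j] + pc$c[, i] * pc$c[, j]
      # viscous grad-grad with linear r weight (exact: int r dA = A rc)
      base <- mu * gg * A * rc
      # swirl-free axisymmetric extra term int phi_i phi_j / r dA (quadrature)
      extra <- mu * A * ((qb[1, i] * qb[1, j]) / rq[, 1] +
                         (qb[2, i] * qb[2, j]) / rq[, 2] +
                         (qb[3, i] * qb[3, j]) / rq[, 3]) / 3
      K_rr[, cij] <- base + extra
      K_zz[, cij] <- base
      # int phi_j r dA = A (3 rc + r_j) / 12 ; int phi_i phi_j dA = A/12 (1+d_ij)
      int_pj_r <- A * (3 * rc + pc$r[, j]) / 12
      int_pipj <- A / 12 * (1 + (i == j))
      G_r[, cij] <- -(pc$b[, i] * int_pj_r + int_pipj)
      G_z[, cij] <- -(pc$c[, i] * int_pj_r)
      S_pp[, cij] <- tau * gg * A * rc
    }
  }
  # periodic identification: nodes on z = L coincide with their z = 0
  # partners; assembly indices are remapped onto the representatives
  map <- seq_len(N)
  if (periodic) {
    top <- which(mesh$nodes[, 2] == mesh$geom$length)
    map[top] <- top - (mesh$nr + 1L) * mesh$nz
    idx[] <- map[idx]
    jdx[] <- map[jdx]
  }
  iv <- as.vector(idx); jv <- as.vector(jdx)
  off_r <- 0L; off_z <- N; off_p <- 2L * N
  Ti <- c(iv + off_r, iv + off_z,            # K_rr, K_zz
          iv + off_r, iv + off_z,            # G_r, G_z (rows u, cols p)
          jv + off_p, jv + off_p,            # D = -G^T (rows p, cols u)
          iv + off_p)                        # -S (rows p, cols p)
  Tj <- c(jv + off_r, jv + off_z,
          jv + off_p, jv + off_p,
          iv + off_r, iv + off_z,
          jv + off_p)
  Tv <- c(as.vector(K_rr), as.vector(K_zz),
          as.vector(G_r), as.vector(G_z),
          -as.vector(G_r), -as.vector(G_z),
          as.vector(S_pp))
  K <- Matrix::sparseMatrix(i = Ti, j = Tj, x = Tv, dims = c(3L * N, 3L * N))
  # pressure-gradient-projection correction (Codina-Blasco): the
  # stabilisation acts on grad(p) minus its lumped nodal P1 projection, so
  # smooth pressure gradients inject no spurious mass. Condensed with a
  # lumped mass matrix into a correction Y added to the pressure block.
  ivn <- as.vector(idx); jvn <- as.vector(jdx)
  # elements in the masked set (by default those touching the axis, where
  # the r-weighted projection weights vanish and the corrected form loses
  # control of pressure modes) keep the plain stabilisation
  if (length(pgp_mask_nodes)) {
    mask_m <- unique(map[pgp_mask_nodes])
    hit <- matrix(matrix(map[el], ncol = 3L) %in% mask_m, ncol = 3L)
    el_ok <- as.numeric(!(hit[, 1] & hit[, 2] & hit[, 3]))
  } else {
    el_ok <- rep(1, n_el)
  }
  w_i <- matrix(0, n_el, 9)          # int phi_i r dA weights per (i, j) pair
  b_j <- matrix(0, n_el, 9); c_j <- matrix(0, n_el, 9)
  tb_i <- matrix(0, n_el, 9); tc_i <- matrix(0, n_el, 9)
  for (i in 1:3) {
    for (j in 1:3) {
      cij <- (i - 1L) * 3L + j
      w_i[, cij] <- el_ok * A * (3 * rc + pc$r[, i]) / 12
      b_j[, cij] <- pc$b[, j]
      c_j[, cij] <- pc$c[, j]
      tb_i[, cij] <- el_ok * tau * A * rc * pc$b[, i] / 3
      tc_i[, cij] <- el_ok * tau * A * rc * pc$c[, i] / 3
    }
  }
  Cr <- Matrix::sparseMatrix(i = ivn, j = jvn, x = as.vector(w_i * b_j),
                             dims = c(N, N))
  Cz <- Matrix::sparseMatrix(i = ivn, j = jvn, x = as.vector(w_i * c_j),
                             dims = c(N, N))
  Tr <- Matrix::sparseMatrix(i = ivn, j = jvn, x = as.vector(tb_i),
                             dims = c(N, N))
  Tz <- Matrix::sparseMatrix(i = ivn, j = jvn, x = as.vector(tc_i),
                             dims = c(N, N))
  Wl <- rowsum_into(as.vector(w_i[, c(1, 5, 9)]),
                    c(map[el[, 1]], map[el[, 2]], map[el[, 3]]), N)
  Winv <- Matrix::Diagonal(N, x = ifelse(Wl > 0, 1 / Wl, 0))
  # scale the projection slightly below 1 so a floor of plain stabilisation
  # survives in thin slivers where the projection equals the gradient
  Y <- stab_pgp * (Tr %*% Winv %*% Cr + Tz %*% Winv %*% Cz)
  Yt <- Matrix::summary(methods::as(Y, "TsparseMatrix"))
  K <- K + Matrix::sparseMatrix(i = Yt$i + 2L * N, j = Yt$j + 2L * N,
                                x = Yt$x, dims = c(3L * N, 3L * N))
  f <- numeric(3L * N)
  if (periodic) {
    # equivalent constant axial body force dp/L (per unit volume)
    fz <- dp / (mesh$geom$length * 1e-9)
    for (i in 1:3) {
      w <- fz * A * (3 * rc + pc$r[, i]) / 12      # int phi_i r dA
      tgt <- off_z + map[el[, i]]
      acc <- rowsum(w, tgt)
      f[as.integer(rownames(acc))] <- f[as.integer(rownames(acc))] + acc[, 1]
      # stabilisation consistency: tau (f, grad q) on the pressure rows
      wq <- tau * fz * pc$c[, i] * A * rc
      tgtq <- off_p + map[el[, i]]
      accq <- rowsum(wq, tgtq)
      f[as.integer(rownames(accq))] <- f[as.integer(rownames(accq))] +
        accq[, 1]
    }
  } else {
    # prescribed-pressure traction on inlet (p = dp) and outlet (p = 0)
    bd <- mesh$boundary
    for (tag in c("inlet", "outlet")) {
      p_amb <- if (tag == "inlet") dp else 0
      if (p_amb == 0) next
      ed <- bd[bd$tag == tag, , drop = FALSE]
      ra <- mesh$nodes[ed$a, 1] * 1e-9
      rb <- mesh$nodes[ed$b, 1] * 1e-9
      len <- abs(rb - ra)
      # traction -p n acts along +z at the inlet (n = (0,-1))
      wa <- p_amb * len * (2 * ra + rb) / 6
      wb <- p_amb * len * (ra + 2 * rb) / 6
      f[off_z + ed$a] <- f[off_z + ed$a] + wa
      f[off_z + ed$b] <- f[off_z + ed$b] + wb
    }
  }
  list(K = K, f = f, N = N, map = map)
}

# rowsum onto a fixed-length vector
rowsum_into <- function(x, group, n) {
  out <- numeric(n)
  acc <- rowsum(x, group)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

# Nodes inside any RBC (constraint set), in the frame of the mesh.
# Fluid films between neighbouring cells that are thinner than ~2 mesh
# layers cannot be resolved; they co-move with the cells (lubrication
# limit), so such axial sliver nodes are constrained as well.
rbc_constrained_nodes <- function(mesh, rbcs) {
  if (length(rbcs) == 0L) return(integer(0))
  r <- mesh$nodes[, 1]; z <- mesh$nodes[, 2]
  L <- mesh$geom$length
  inside <- rep(FALSE, length(r))
  for (cell in rbcs) {
    inside <- inside | rbc_contains(cell, r, z)
    # periodic images for cells near the ends
    if (mesh$geom$periodic_axial) {
      shifted_lo <- cell; shifted_lo$z_center <- cell$z_center - L
      shifted_hi <- cell; shifted_hi$z_center <- cell$z_center + L
      inside <- inside | rbc_contains(shifted_lo, r, z) |
        rbc_contains(shifted_hi, r, z)
    }
  }
  M <- matrix(inside, nrow = mesh$nr + 1L)       # radial x axial grid
  nzc <- ncol(M)
  for (i in seq_len(nrow(M))) {
    row <- M[i, ]
    if (!any(row) || all(row)) next
    rr <- rle(row)
    ends <- cumsum(rr$lengths)
    starts <- ends - rr$lengths + 1L
    for (k in seq_along(rr$values)) {
      if (rr$values[k] || rr$lengths[k] > 2L) next
      left_in <- if (k > 1L) TRUE
                 else mesh$geom$periodic_axial && row[nzc]
      right_in <- if (k < length(rr$values)) TRUE
                  else mesh$geom$periodic_axial && row[1L]
      if (left_in && right_in) M[i, starts[k]:ends[k]] <- TRUE
    }
  }
  which(as.vector(M))
}

#' Solve the quasi-static axisymmetric flow problem
#'
#' Solves incompressible Stokes flow (the inertial term is negligible at
#' capillary Reynolds numbers ~1e-3) in the meridional plane with P1/P1
#' elements and GLS pressure stabilisation. No-slip on the wall, symmetry on
#' the axis, prescribed pressure drop through traction boundary conditions at
#' the ends, and rigid-body velocity constraints (`v_r = 0`,
#' `v_z = rbc_velocity`) at nodes inside each red blood cell.
#'
#' @param mesh A [build_mesh()] result.
#' @param fluid A [fluid_properties()].
#' @param rbcs List of [rbc_agent()] obstacles (may be empty).
#' @param rbc_velocity Common axial speed of the RBCs in um/s (scalar).
#' @param mu Dynamic viscosity in Pa.s; defaults to the plasma viscosity.
#'   Pass [effective_viscosity()] output for cellular runs.
#' @param stab_alpha GLS stabilisation coefficient. Default 0.01.
#' @param stab_pgp Fraction of the pressure-gradient-projection correction
#'   applied to the stabilisation term (0 = plain stabilisation, robust
#'   default; values near 1 reduce the stabilisation's mass perturbation
#'   but can admit pressure modes near velocity-constrained regions).
#' @return An object of class `flow_field`: nodal `v_r`, `v_z` (um/s),
#'   `pressure` (Pa), the `mesh`, `mu`, `dp`, `rbcs`, `rbc_velocity`,
#'   the RBC-constrained node set `rbc_nodes` and the net axial reaction
#'   force `rbc_force` (N) on the RBC set.
#' @export
solve_flow <- function(mesh, fluid, rbcs = list(), rbc_velocity = 0,
                       mu = NULL, stab_alpha = 0.01, stab_pgp = 0) {
  if (is.null(mu)) mu <- fluid$plasma_viscosity
  dp <- fluid$pressure_drop
  if (is.null(dp))
    dp <- calibrate_pressure_drop(mesh$geom, mu, fluid$v_center_target)
  periodic <- mesh$geom$periodic_axial
  tag <- mesh$node_tag
  wall <- which(tag == "wall")
  axis <- which(tag == "axis")
  rbc_nodes <- rbc_constrained_nodes(mesh, rbcs)
  rbc_nodes <- setdiff(rbc_nodes, wall)
  near_axis <- which(mesh$nodes[, 1] < 3.5 * mesh$dr)
  sys <- assemble_stokes(mesh, mu, dp, stab_alpha, periodic = periodic,
                         stab_pgp = stab_pgp, pgp_mask_nodes = near_axis)
  N <- sys$N
  map <- sys$map
  # constrained dofs and values (SI m/s), on representative nodes
  wall_m <- unique(map[wall]); axis_m <- unique(map[axis])
  rbc_m <- setdiff(unique(map[rbc_nodes]), wall_m)
  con <- c(wall_m, axis_m, rbc_m,            # u_r = 0
           N + wall_m, N + rbc_m)            # u_z
  val <- c(rep(0, length(wall_m) + length(axis_m) + length(rbc_m)),
           rep(0, length(wall_m)),
           rep(rbc_velocity * 1e-6, length(rbc_m)))
  keep <- !duplicated(con)
  con <- con[keep]; val <- val[keep]
  # orphaned periodic-image dofs (empty rows) and, in periodic mode, one
  # pinned pressure dof fixing the pressure nullspace
  orphan <- which(map != seq_len(N))
  if (length(orphan)) {
    con <- c(con, orphan, N + orphan, 2L * N + orphan)
    val <- c(val, rep(0, 3L * length(orphan)))
  }
  if (periodic) {
    pin <- map[which(tag == "interior")[1]]
    con <- c(con, 2L * N + pin)
    val <- c(val, 0)
  }
  # pressure is meaningless deep inside an RBC (every incident element is
  # fully velocity-constrained): pin it to avoid an ill-conditioned island
  if (length(rbc_m)) {
    vcon <- c(wall_m, rbc_m)                 # both components constrained
    elm <- matrix(map[mesh$elements], ncol = 3L)
    full <- matrix(elm %in% vcon, ncol = 3L)
    full_el <- full[, 1] & full[, 2] & full[, 3]
    n_inc <- rowsum_into(rep(1, 3L * nrow(elm)), as.vector(elm), N)
    n_full <- rowsum_into(rep(as.numeric(full_el), 3L), as.vector(elm), N)
    deep <- intersect(rbc_m, which(n_inc > 0 & n_full == n_inc))
    if (length(deep)) {
      con <- c(con, 2L * N + deep)
      val <- c(val, rep(0, length(deep)))
    }
  }
  keep <- !duplicated(con)
  con <- con[keep]; val <- val[keep]
  K <- sys$K; f <- sys$f
  f_full <- f
  # eliminate: move known columns to RHS, identity rows for constraints
  f <- f - as.numeric(K[, con, drop = FALSE] %*% val)
  free <- setdiff(seq_len(3L * N), con)
  sol <- numeric(3L * N)
  sol[con] <- val
  sol[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE],
                                        f[free]))
  resid <- as.numeric(K %*% sol - f_full)
  # copy representative values onto periodic-image nodes for output
  if (length(orphan)) {
    sol[orphan] <- sol[map[orphan]]
    sol[N + orphan] <- sol[N + map[orphan]]
    sol[2L * N + orphan] <- sol[2L * N + map[orphan]]
  }
  # net axial reaction on the RBC constraint set (per 2*pi radians omitted
  # consistently; only the zero crossing matters)
  rbc_force <- if (length(rbc_m)) sum(resid[N + rbc_m]) else 0
  structure(list(v_r = sol[seq_len(N)] * 1e6,
                 v_z = sol[N + seq_len(N)] * 1e6,
                 pressure = sol[2L * N + seq_len(N)],
                 mesh = mesh, mu = mu, dp = dp,
                 rbcs = rbcs, rbc_velocity = rbc_velocity,
                 rbc_nodes = rbc_nodes, rbc_force = rbc_force,
                 free_resid = max(abs(resid[free]))),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(paste0("<flow_field> %d nodes, mu %.3g Pa.s, dp %.3g Pa, ",
                     "%d RBC(s) at %.0f um/s, max |v_z| %.0f um/s\n"),
              nrow(x$mesh$nodes), x$mu, x$dp, length(x$rbcs),
              x$rbc_velocity, max(abs(x$v_z))))
  invisible(x)
}

#' Force-free speed of the red blood cells
#'
#' RBCs move at the speed set by the pressure gradient and viscosity: the
#' speed at which the net axial hydrodynamic traction on the cell boundary
#' vanishes. For Stokes flow the reaction force is affine in the driven
#' speed, so two solves bracket and solve the zero exactly.
#'
#' @inheritParams solve_flow
#' @return List with `velocity` (um/s), the converged `field` at that speed
#'   and the residual `force` (should be ~0).
#' @export
rbc_force_free_velocity <- function(mesh, fluid, rbcs, mu = NULL,
                                    stab_alpha = 0.01) {
  if (length(rbcs) == 0L) stop("no RBCs supplied")
  if (is.null(mu)) mu <- fluid$plasma_viscosity
  dp <- fluid$pressure_drop
  if (is.null(dp))
    dp <- calibrate_pressure_drop(mesh$geom, mu, fluid$v_center_target)
  v_ref <- poiseuille_profile(mesh$geom, dp, mu, 0)  # centreline speed
  f0 <- solve_flow(mesh, fluid, rbcs, 0, mu, stab_alpha)
  f1 <- solve_flow(mesh, fluid, rbcs, v_ref, mu, stab_alpha)
  slope <- (f1$rbc_force - f0$rbc_force) / v_ref
  if (slope == 0) stop("could not bracket the force-free RBC speed")
  v_star <- -f0$rbc_force / slope
  field <- solve_flow(mesh, fluid, rbcs, v_star, mu, stab_alpha)
  list(velocity = v_star, field = field, force = field$rbc_force)
}

#' Interpolate the flow field at 3D particle positions
#'
#' Maps the axisymmetric nodal field to Cartesian velocities at arbitrary
#' points using the containing element's P1 shape functions (continuous
#' across element edges): `v_x = v_r cos(theta)`, `v_y = v_r sin(theta)`.
#'
#' @param field A [solve_flow()] result.
#' @param points n x 3 matrix of (x, y, z) positions in nm.
#' @param shift Axial shift in nm applied before lookup (lab frame to the
#'   co-moving RBC frame in which the field is steady). Default 0.
#' @return n x 3 matrix of (v_x, v_y, v_z) in um/s.
#' @export
interpolate_velocity <- function(field, points, shift = 0) {
  mesh <- field$mesh
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  rho <- sqrt(x^2 + y^2)
  R <- mesh$geom$radius; L <- mesh$geom$length
  if (any(rho > R * (1 + 1e-9)))
    stop("point outside the vessel wall (rho > radius)")
  rho <- pmin(rho, R)
  zq <- z - shift
  if (mesh$geom$periodic_axial) {
    zq <- zq %% L
  } else if (any(zq < -1e-9 | zq > L + 1e-9)) {
    stop("point outside the vessel ends (z out of [0, length])")
  }
  zq <- pmin(pmax(zq, 0), L * (1 - 1e-12))
  i <- pmin(floor(rho / mesh$dr), mesh$nr - 1L)
  j <- pmin(floor(zq / mesh$dz), mesh$nz - 1L)
  xi <- rho / mesh$dr - i
  eta <- zq / mesh$dz - j
  nid <- function(ii, jj) ii + (mesh$nr + 1L) * jj + 1L
  n00 <- nid(i, j); n10 <- nid(i + 1L, j)
  n01 <- nid(i, j + 1L); n11 <- nid(i + 1L, j + 1L)
  lower <- xi + eta <= 1
  w00 <- ifelse(lower, 1 - xi - eta, 0)
  w10 <- ifelse(lower, xi, 1 - eta)
  w01 <- ifelse(lower, eta, 1 - xi)
  w11 <- ifelse(lower, 0, xi + eta - 1)
  vr <- w00 * field$v_r[n00] + w10 * field$v_r[n10] +
        w01 * field$v_r[n01] + w11 * field$v_r[n11]
  vz <- w00 * field$v_z[n00] + w10 * field$v_z[n10] +
        w01 * field$v_z[n01] + w11 * field$v_z[n11]
  ct <- ifelse(rho > 0, x / rho, 1)
  st <- ifelse(rho > 0, y / rho, 0)
  cbind(vx = vr * ct, vy = vr * st, vz = vz)
}

#' Axial volumetric flux through a cross-section
#'
#' Integrates `v_z 2 pi r dr` over the node column nearest to `z`; used for
#' the mass-conservation invariant.
#'
#' @param field A [solve_flow()] result.
#' @param z Axial position in nm.
#' @return Flux in um^3/s.
#' @export
cross_section_flux <- function(field, z) {
  mesh <- field$mesh
  j <- round(z / mesh$dz)
  j <- min(max(j, 0), mesh$nz)
  idx <- (0:mesh$nr) + (mesh$nr + 1L) * j + 1L
  r <- mesh$nodes[idx, 1] * 1e-3           # nm -> um
  vz <- field$v_z[idx]                     # um/s
  # trapezoid on v_z * 2 pi r
  f <- 2 * pi * r * vz
  sum(diff(r) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}
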