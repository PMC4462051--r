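test_that("effective viscosity is anchored at plasma and superlinear", {
  mu_p <- 1.2e-3
  expect_equal(effective_viscosity(0, mu_p), mu_p)
  expect_equal(effective_viscosity(0.45, mu_p),
               mu_p * (1 + 2.5 * 0.45 + 7.35 * 0.45^2))
  expect_equal(effective_viscosity(0.45, mu_p), 4.336e-3, tolerance = 1e-3)
  H <- seq(0, 0.45, by = 0.05)
  mu <- effective_viscosity(H, mu_p)
  expect_true(all(diff(mu) > 0))
  # superlinear: increments grow
  expect_true(all(diff(diff(mu)) > 0))
  mu_e <- effective_viscosity(H, mu_p, "exponential")
  expect_equal(mu_e[1], mu_p)
  expect_true(all(diff(mu_e) > 0))
  expect_error(effective_viscosity(1.2, mu_p), "0, 1")
})

test_that("Reynolds number stays deep in the laminar regime", {
  expect_equal(reynolds_number(1000, 1e-3, 8e-6, 1e-3), 8e-3)
  expect_equal(reynolds_number(1000, 0, 8e-6, 1e-3), 0)
  # default capillary conditions: mean speed ~ half the 5500 um/s centreline
  Re <- reynolds_number(1000, 2750e-6, 8e-6, 1.2e-3)
  expect_lt(Re, 2400 / 1e4)
  expect_error(reynolds_number(1000, 1e-3, 8e-6, 0), "> 0")
})

test_that("Poiseuille closed form and pressure calibration are consistent", {
  geom <- vessel_geometry()
  mu <- 1.2e-3
  dp <- calibrate_pressure_drop(geom, mu, 5500)
  expect_equal(dp, 82.5)
  expect_equal(poiseuille_profile(geom, dp, mu, 0), 5500)
  expect_equal(poiseuille_profile(geom, dp, mu, geom$radius), 0)
  # centreline speed is twice the cross-section mean of the parabola
  r <- seq(0, geom$radius, length.out = 2000)
  v <- poiseuille_profile(geom, dp, mu, r)
  v_mean <- sum(v * r) * diff(r)[1] * 2 / geom$radius^2
  expect_equal(poiseuille_profile(geom, dp, mu, 0), 2 * v_mean,
               tolerance = 1e-5)
  expect_error(poiseuille_profile(geom, dp, mu, 4001), "radius")
})

test_that("FEM solution matches the Poiseuille oracle and converges", {
  geom <- vessel_geometry()
  fluid <- fluid_properties()
  mesh <- build_mesh(geom, nr = 40, nz = 24)
  f <- solve_flow(mesh, fluid)
  v_ex <- poiseuille_profile(geom, f$dp, f$mu, mesh$nodes[, 1])
  err1 <- max(abs(f$v_z - v_ex)) / max(v_ex)
  expect_lt(err1, 0.01)
  expect_lt(max(abs(f$v_r)), 1e-3 * max(f$v_z))
  # halving element size reduces the max error at least 2x
  mesh2 <- build_mesh(geom, nr = 80, nz = 48)
  f2 <- solve_flow(mesh2, fluid)
  v_ex2 <- poiseuille_profile(geom, f2$dp, f2$mu, mesh2$nodes[, 1])
  err2 <- max(abs(f2$v_z - v_ex2)) / max(v_ex2)
  expect_lt(err2, err1 / 2)
  # velocity decreases monotonically from axis to wall
  col <- f$v_z[seq_len(mesh$nr + 1L) + (mesh$nr + 1L) * 10L]
  expect_true(all(diff(col) < 0))
})

test_that("axial volumetric flux is conserved along the vessel", {
  geom <- vessel_geometry()
  fluid <- fluid_properties()
  mesh <- build_mesh(geom, nr = 24, nz = 120)
  f <- solve_flow(mesh, fluid)
  fx <- vapply(c(0, 12500, 25000, 37500), function(z)
    cross_section_flux(f, z), numeric(1))
  expect_lt((max(fx) - min(fx)) / mean(fx), 0.01)
  # with RBCs at the force-free speed, within 3%
  mu <- effective_viscosity(0.107, fluid$plasma_viscosity)
  rbcs <- place_rbcs(3, geom)
  ff <- rbc_force_free_velocity(mesh, fluid, rbcs, mu = mu)
  fx2 <- vapply(seq(0, 45000, 5000), function(z)
    cross_section_flux(ff$field, z), numeric(1))
  expect_lt((max(fx2) - min(fx2)) / mean(fx2), 0.03)
})

test_that("gap flow past a near-lumen cell approaches the annular drag flow", {
  geom <- vessel_geometry()
  # quasi-infinite inner cylinder: shell spanning 40 um of the periodic box
  a <- 3600
  cell <- rbc_agent(z_center = 25000, effective_radius = a,
                    cell_volume = pi * (a / 1000)^2 * 40, cap_depth = 100)
  mesh <- build_mesh(geom, nr = 80, nz = 100)
  v <- 1000
  f <- solve_flow(mesh, fluid_properties(pressure_drop = 1e-12),
                  list(cell), v)
  rr <- seq(a, geom$radius, by = 50)
  j_mid <- 50L
  idx <- rr / 50 + (mesh$nr + 1L) * j_mid + 1L
  v_num <- f$v_z[idx]
  v_th <- v * log(geom$radius / rr) / log(geom$radius / a)
  expect_lt(max(abs(v_num - v_th)) / v, 0.05)
})

test_that("force-free RBC speed sits between mean and centreline flow", {
  geom <- vessel_geometry()
  fluid <- fluid_properties()
  mesh <- build_mesh(geom, nr = 24, nz = 120)
  mu <- effective_viscosity(0.107, fluid$plasma_viscosity)
  rbcs <- place_rbcs(3, geom)
  ff <- rbc_force_free_velocity(mesh, fluid, rbcs, mu = mu)
  v_centre <- poiseuille_profile(geom, ff$field$dp, mu, 0)
  expect_gt(ff$velocity, v_centre / 2)
  expect_lt(ff$velocity, v_centre)
  # defining condition: net axial traction vanishes
  expect_lt(abs(ff$force), 1e-6 * abs(solve_flow(mesh, fluid, rbcs, 0,
                                                 mu)$rbc_force))
  # vanishing-radius limit recovers the centreline speed
  tiny <- list(rbc_agent(z_center = 25000, effective_radius = 300,
                         cell_volume = 0.5, cap_depth = 100))
  ff2 <- rbc_force_free_velocity(mesh, fluid, tiny)
  v_c2 <- poiseuille_profile(geom, ff2$field$dp, ff2$field$mu, 0)
  expect_lt(abs(ff2$velocity - v_c2) / v_c2, 0.05)
})

test_that("velocity interpolation honours boundaries and the parabola", {
  geom <- vessel_geometry()
  fluid <- fluid_properties()
  mesh <- build_mesh(geom, nr = 32, nz = 32)
  f <- solve_flow(mesh, fluid)
  v_max <- max(f$v_z)
  on_wall <- interpolate_velocity(f, c(4000, 0, 25000))
  expect_equal(as.numeric(on_wall), c(0, 0, 0))
  on_axis <- interpolate_velocity(f, c(0, 0, 12000))
  expect_equal(as.numeric(on_axis[1:2]), c(0, 0))
  # r = R/2 on the parabola: v_z = 0.75 v_max
  mid <- interpolate_velocity(f, c(2000 / sqrt(2), 2000 / sqrt(2), 30000))
  expect_equal(mid[3] / v_max, 0.75, tolerance = 5e-3)
  expect_error(interpolate_velocity(f, c(4100, 0, 0)), "outside")
  # periodic wrap: shifting z by the vessel length changes nothing
  p1 <- interpolate_velocity(f, c(1000, 500, 12345))
  p2 <- interpolate_velocity(f, c(1000, 500, 12345 + geom$length))
  expect_equal(p1, p2)
})

test_that("cellular phase: near-lumen cells drag the trapped fluid", {
  # zero pressure drop, wide closely spaced cells driven at v: fluid in the
  # short inter-cell gaps cannot develop a profile and moves as a plug at
  # the cell speed (gap length well below the vessel radius)
  geom <- vessel_geometry()
  v <- 1000
  cells <- lapply(c(6250, 18750, 31250, 43750), function(zc)
    rbc_agent(z_center = zc, effective_radius = 3800,
              cell_volume = pi * 3.8^2 * 10, cap_depth = 100))
  mesh <- build_mesh(geom, nr = 80, nz = 200)
  f <- solve_flow(mesh, fluid_properties(pressure_drop = 1e-12), cells, v)
  # probe the axis midway between two cells
  probe <- interpolate_velocity(f, c(0, 0, 12500))
  expect_equal(probe[3], v, tolerance = 0.05)
})

test_that("mesh construction is sound", {
  geom <- vessel_geometry()
  mesh <- build_mesh(geom, nr = 10, nz = 20)
  expect_true(all(element_areas(mesh) > 0))
  expect_equal(nrow(mesh$elements), 2 * 10 * 20)
  expect_true(all(mesh$nodes[mesh$node_tag == "axis", 1] == 0))
  expect_true(all(mesh$nodes[mesh$node_tag == "wall", 1] == geom$radius))
  # every boundary edge tagged exactly once
  expect_equal(nrow(mesh$boundary), 2 * 20 + 2 * 10)
  expect_false(any(duplicated(mesh$boundary[, c("a", "b")])))
  expect_error(build_mesh(geom, 2, 2), "at least")
})
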