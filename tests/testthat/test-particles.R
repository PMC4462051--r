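test_that("Stokes-Einstein diffusion coefficient and sigma scale correctly", {
  D50 <- diffusion_coefficient(310, 1.2e-3, 50)
  expect_equal(D50, 3.78e-12, tolerance = 2e-3)
  expect_equal(diffusion_coefficient(310, 1.2e-3, 5), 10 * D50)
  expect_equal(diffusion_coefficient(310, 1.2e-3, 100), D50 / 2)
  expect_error(diffusion_coefficient(310, 1.2e-3, 0), "> 0")
  expect_equal(brownian_sigma(3.78e-12, 1e-4), 27.5, tolerance = 1e-3)
  expect_equal(brownian_sigma(0, 1e-4), 0)
  expect_equal(brownian_sigma(D50, 4e-4), 2 * brownian_sigma(D50, 1e-4))
  expect_error(brownian_sigma(-1e-12, 1e-4), ">= 0")
})

test_that("polar Box-Muller draws are Gaussian with the requested sigma", {
  set.seed(42)
  sigma <- 10
  x <- brownian_step(brownian_stepper(3.78e-12, 1e-4) , 1)
  expect_equal(dim(x), c(1L, 3L))
  g <- as.vector(brownian_step(sigma, 4e4))   # 1.2e5 draws
  n <- length(g)
  expect_lt(abs(mean(g)), 4 * sigma / sqrt(n))
  expect_lt(abs(stats::var(g) - sigma^2) / sigma^2, 0.05)
  expect_gt(stats::ks.test(g / sigma, "pnorm")$p.value, 0.01)
  expect_equal(brownian_step(0, 5), matrix(0, 5, 3))
})

test_that("free diffusion reproduces MSD = 6 D t", {
  set.seed(7)
  geom <- vessel_geometry()
  D <- diffusion_coefficient(310, 1.2e-3, 50)
  dt <- 1e-4
  sigma <- brownian_sigma(D, dt)
  n <- 2000
  pos0 <- cbind(rep(0, n), 0, 25000)
  pos <- pos0
  n_steps <- 30
  for (s in seq_len(n_steps))
    pos <- advance_particles(pos, 50, sigma, NULL, dt, geom,
                             laminar_on = FALSE)
  t_tot <- n_steps * dt
  expect_equal(msd(pos, pos0), 6 * D * t_tot * 1e18,   # m^2 -> nm^2
               tolerance = 0.05)
  # mean displacement is zero within the CLT bound
  expect_lt(max(abs(colMeans(pos - pos0))),
            4 * sigma * sqrt(n_steps) / sqrt(n))
})

test_that("advection arithmetic is exact for uniform flow", {
  geom <- vessel_geometry()
  f <- uniform_field(geom, 1000)
  pos <- cbind(c(500, 1500), c(0, 200), c(10000, 20000))
  out <- advance_particles(pos, 50, 0, f, 1e-4, geom, brownian_on = FALSE)
  expect_equal(out[, 3], pos[, 3] + 100)     # 1000 um/s * 1e-4 s = 100 nm
  expect_equal(out[, 1:2], pos[, 1:2])
  # both toggles off freezes the particle
  frozen <- advance_particles(pos, 50, 10, f, 1e-4, geom,
                              laminar_on = FALSE, brownian_on = FALSE)
  expect_equal(frozen, pos)
})

test_that("wall reflection mirrors about the accessible radius", {
  geom <- vessel_geometry()
  inside <- c(3000, 0, 5000)
  expect_equal(reflect_at_wall(inside, 50, geom), inside)
  # 25 nm past the accessible radius 3950 reflects to 3925
  out <- reflect_at_wall(c(3975, 0, 5000), 50, geom)
  expect_equal(out, c(3925, 0, 5000))
  # z is conserved and the constraint holds for random overshoots
  set.seed(11)
  th <- runif(200, 0, 2 * pi)
  rho <- runif(200, 3900, 4100)
  pos <- cbind(rho * cos(th), rho * sin(th), runif(200, 0, 5e4))
  ref <- reflect_at_wall(pos, 50, geom)
  expect_equal(ref[, 3], pos[, 3])
  expect_true(all(sqrt(ref[, 1]^2 + ref[, 2]^2) + 50 <= 4000 + 1e-9))
  # idempotent on interior points
  expect_equal(reflect_at_wall(ref, 50, geom), ref)
})

test_that("RBC excluded volume pushes particles to tangential contact", {
  geom <- vessel_geometry()
  rbc <- rbc_agent(z_center = 25000)
  rbcs <- list(rbc)
  far <- cbind(3950, 0, 5000)
  expect_equal(resolve_rbc_overlap(far, 50, rbcs, geom), far)
  # particle centre buried inside the cap emerges at surface distance r
  buried <- cbind(1000, 0, 25000 + rbc$thickness / 2 + 0.6 * rbc$cap_depth)
  outp <- resolve_rbc_overlap(buried, 50, rbcs, geom, n_profile = 512)
  rho <- sqrt(outp[1, 1]^2 + outp[1, 2]^2)
  d <- rbc_signed_distance(rbc, rho, outp[1, 3], n_profile = 2048)
  expect_equal(d, 50, tolerance = 2e-3)
  # property: random points near the cell end up non-overlapping
  set.seed(13)
  pts <- cbind(runif(100, 0, 3000), 0,
               25000 + runif(100, -4000, 4000))
  res <- resolve_rbc_overlap(pts, 50, rbcs, geom, n_profile = 256)
  rho_r <- sqrt(res[, 1]^2 + res[, 2]^2)
  dist <- rbc_signed_distance(rbc, rho_r, res[, 3], n_profile = 1024)
  expect_true(all(dist >= 50 - 0.5))
})

test_that("Brownian share of MSD dominates at the wall, not the centre", {
  cfg <- simulation_config(particles = list(n = 15,
                                            population = list(type = "mono",
                                                              diameter = 100)),
                           mesh = list(nr = 20, nz = 100), seed = 5)
  centre <- msd_decomposition(cfg, "centre", n_particles = 15)
  wall <- msd_decomposition(cfg, "wall", n_particles = 15)
  expect_gt(wall$share_brownian, 10 * centre$share_brownian)
  expect_gt(centre$share_laminar, 0.99)
})
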