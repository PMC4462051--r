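test_that("configuration validation is strict and exhaustive", {
  cfg <- simulation_config()
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$haematocrit, 0.107)
  expect_equal(cfg$time$dt, 1e-4)
  expect_error(simulation_config(geometry = list(radios = 4000)),
               "unknown config key.*geometry")
  expect_error(simulation_config(haematocrit = 0.9), "0, 0.45")
  # every violation is listed, not just the first
  err <- tryCatch(simulation_config(haematocrit = -1,
                                    time = list(total = 1e-6, dt = 1e-4,
                                                dt_pore = 1e-3)),
                  error = conditionMessage)
  expect_match(err, "haematocrit")
  expect_match(err, "total time")
  expect_match(err, "dt_pore")
})

test_that("YAML configuration round-trips", {
  cfg <- simulation_config(haematocrit = 0.2,
                           particles = list(n = 44),
                           seed = 99L)
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(cfg, f)
  cfg2 <- load_config(f)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  # unknown top-level key rejected by name
  txt <- readLines(f)
  writeLines(c(txt, "banana: 1"), f)
  expect_error(load_config(f), "banana")
})

test_that("degenerate simulations advance time and freeze as requested", {
  cfg <- simulation_config(haematocrit = 0, particles = list(n = 0),
                           time = list(total = 5e-4, record_every = 0),
                           mesh = list(nr = 8, nz = 16))
  res <- simulate_capillary(cfg)
  expect_equal(res$n_steps, 5L)
  expect_equal(length(res$diameter), 0L)
  # both toggles off: positions frozen over the run
  cfg2 <- simulation_config(haematocrit = 0, particles = list(n = 10),
                            time = list(total = 1e-3, record_every = 1),
                            toggles = list(brownian_on = FALSE,
                                           laminar_on = FALSE),
                            mesh = list(nr = 8, nz = 16), seed = 3)
  res2 <- simulate_capillary(cfg2)
  expect_equal(res2$trajectory[1, , ],
               res2$trajectory[dim(res2$trajectory)[1], , ])
})

test_that("one Brownian-free step advances particles by u dt", {
  cfg <- simulation_config(haematocrit = 0, particles = list(n = 12),
                           time = list(total = 1e-4, record_every = 1),
                           toggles = list(brownian_on = FALSE),
                           mesh = list(nr = 16, nz = 32), seed = 9)
  res <- simulate_capillary(cfg)
  x0 <- res$trajectory[1, , ]
  x1 <- res$trajectory[2, , ]
  u <- unname(interpolate_velocity(res$field, x0))
  expect_equal(x1, x0 + u * 1e-4 * 1e3, tolerance = 1e-10)
})

test_that("identical seeds give byte-identical outputs; particles conserved", {
  cfg <- fast_config(seed = 17,
                     fenestrations = list(density = 1, diameter = 240))
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(f1, f2)))
  r1 <- simulate_capillary(cfg)
  write_metrics_json(r1$summary, f1)
  r2 <- simulate_capillary(cfg)
  write_metrics_json(r2$summary, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(r1$position, r2$position)
  # status partition covers the population at readout
  expect_equal(unname(sum(r1$summary$counts)), cfg$particles$n)
  expect_true(all(r1$status %in% c("free", "in_pore", "translocated")))
  # time bookkeeping
  expect_equal(r1$n_steps * cfg$time$dt, cfg$time$total)
})

test_that("run outputs land in the run directory", {
  dir <- tempfile("capsim-run-")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- fast_config(seed = 23, output = list(dir = dir))
  res <- simulate_capillary(cfg)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "metrics.json")))
  expect_true(file.exists(file.path(dir, "events.csv")))
  expect_true(file.exists(file.path(dir, "trajectory.csv")))
  expect_true(file.exists(file.path(dir, "flow.vtk")))
  # VTK header is well-formed
  head4 <- readLines(file.path(dir, "flow.vtk"), n = 4)
  expect_match(head4[1], "vtk DataFile")
  expect_equal(head4[4], "DATASET UNSTRUCTURED_GRID")
  # config copy reloads
  expect_s3_class(load_config(file.path(dir, "config.yaml")),
                  "simulation_config")
})

test_that("haematocrit sweep driver returns the expected table", {
  cfg <- simulation_config(mesh = list(nr = 16, nz = 100), seed = 2)
  tab <- run_experiment_haematocrit_sweep(cfg, c(0, 0.107), replicates = 2)
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("H", "replicate", "adf", "rbc_velocity") %in%
                  names(tab)))
  expect_lt(max(tab$adf[tab$H == 0]), 1e-6)
  expect_gt(min(tab$adf[tab$H == 0.107]), 0)
  expect_error(run_experiment_haematocrit_sweep(cfg, 0.6), "0, 0.45")
})

test_that("force-balance traces behave at the two start positions", {
  cfg <- simulation_config(particles = list(n = 8,
                                            population = list(type = "mono",
                                                              diameter = 100)),
                           mesh = list(nr = 16, nz = 80), seed = 29)
  fb_c <- run_experiment_force_balance(cfg, "centre", n_particles = 8)
  # laminar-only from the centre is a straight axial line
  traj <- fb_c$trajectories$laminar_only
  expect_equal(max(abs(traj[, , 1] - traj[1, , 1][col(traj[, , 1])])), 0)
  expect_true(all(diff(fb_c$laminar_only$msd) >= 0))
  fb_w <- run_experiment_force_balance(cfg, "wall", n_particles = 8)
  # axial displacement from the wall is smaller than from the centre
  expect_lt(tail(fb_w$laminar_only$msd, 1), tail(fb_c$laminar_only$msd, 1))
  # brownian-only has no systematic drift (CLT bound over the ensemble)
  bt <- fb_c$trajectories$brownian_only
  disp <- bt[dim(bt)[1], , ] - bt[1, , ]
  D <- diffusion_coefficient(310, 1.2e-3, 50)
  sig_tot <- sqrt(2 * D * 0.003) * 1e9
  expect_lt(max(abs(colMeans(disp))), 4 * sig_tot / sqrt(nrow(disp)))
})

test_that("RBC volume exclusion shifts particles toward the vessel wall", {
  mrp <- sapply(c(0, 0.12), function(H) {
    cfg <- simulation_config(haematocrit = H, particles = list(n = 300),
                             time = list(total = 0.01, record_every = 0),
                             mesh = list(nr = 20, nz = 100), seed = 77)
    simulate_capillary(cfg)$summary$mean_radial_position
  })
  # acellular: uniform in the cross-section, mean ~ (2/3) accessible radius
  expect_equal(mrp[1], 2 / 3 * 3950, tolerance = 0.02)
  # cells occupy the core, pushing the population outward
  expect_gt(mrp[2], mrp[1])
})
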