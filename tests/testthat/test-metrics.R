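test_that("radial velocity and dispersion factor follow their definitions", {
  expect_equal(radial_velocity(0, 0), 0)
  expect_equal(radial_velocity(3, 4), 5)
  # rotation invariance of the radial speed
  th <- runif(20, 0, 2 * pi)
  expect_equal(radial_velocity(5 * cos(th), 5 * sin(th)), rep(5, 20))
  expect_equal(dispersion_factor(0, 123), 0)
  expect_equal(dispersion_factor(5, 10), 0.5)
  expect_equal(dispersion_factor(5 * 3, 10 * 3), 0.5)   # homogeneity
  expect_true(is.nan(dispersion_factor(5, 0)))
  expect_equal(dispersion_factor(0, 0), 0)
})

test_that("average dispersion factor handles masks and synthetic fields", {
  geom <- vessel_geometry()
  f <- uniform_field(geom, 1000, nr = 8, nz = 16)
  expect_equal(average_dispersion_factor(f)$adf, 0)
  # constant DF = 0.2 everywhere
  f2 <- f
  f2$v_r <- rep(200, length(f$v_z))
  a <- average_dispersion_factor(f2)
  expect_equal(a$adf, 0.2)
  expect_equal(a$n_undefined, 0)
  # hand-built element mean: three DF populations average to their mean
  expect_equal(mean(c(0, 0.1, 0.5)), 0.2)
})

test_that("MSD obeys the static, ballistic and diffusive laws", {
  expect_equal(msd(c(1, 2, 3), c(1, 2, 3)), 0)
  # constant velocity v for time t: MSD = (|v| t)^2
  v <- c(100, 0, 200)                     # nm per step
  x0 <- matrix(rep(c(5, 5, 5), 4), ncol = 3, byrow = TRUE)
  xt <- sweep(x0, 2, 10 * v, "+")         # after 10 steps
  expect_equal(msd(xt, x0), sum((10 * v)^2))
  expect_error(msd(matrix(0, 2, 3), matrix(0, 3, 3)), "mismatch")
  traj <- array(0, c(3, 2, 3))
  traj[2, , 3] <- 10
  traj[3, , 3] <- 20
  ser <- msd_series(traj, c(0, 1, 2))
  expect_equal(ser$msd, c(0, 100, 400))
})

test_that("binding-range fraction and mean radial position count correctly", {
  geom <- vessel_geometry()
  # 3 of 10 particles within 20 nm of the wall (gap = R - rho - r)
  rho <- c(3930, 3940, 3935, rep(2000, 7))
  pos <- cbind(rho, 0, 0)
  expect_equal(fraction_within_binding_range(pos, 50, geom), 30)
  # touching the wall counts; the axis does not
  expect_equal(fraction_within_binding_range(cbind(3950, 0, 0), 50, geom),
               100)
  expect_equal(fraction_within_binding_range(cbind(0, 0, 0), 50, geom), 0)
  expect_error(fraction_within_binding_range(matrix(0, 0, 3), 50, geom),
               "empty")
  expect_equal(mean_radial_position(cbind(0, 0, 1:5)), 0)
  # uniform-in-cross-section: mean radial position -> (2/3) R_a
  set.seed(51)
  Ra <- 3950
  r <- Ra * sqrt(runif(4e4))
  th <- runif(4e4, 0, 2 * pi)
  m <- mean_radial_position(cbind(r * cos(th), r * sin(th), 0))
  expect_equal(m, 2 / 3 * Ra, tolerance = 0.005)
})

test_that("specificity ratio and score combine uptake as specified", {
  expect_equal(specificity_ratio(30, 10), 3)
  expect_equal(specificity_ratio(7, 7), 1)
  expect_identical(specificity_ratio(5, 0), Inf)
  expect_true(is.nan(specificity_ratio(0, 0)))
  expect_error(specificity_ratio(-1, 1), ">= 0")
  expect_equal(specificity_score(30, 10), 0.9)
  expect_equal(specificity_score(0, 10), 0)
  # quadratic in tumour uptake at fixed normal uptake
  expect_equal(specificity_score(20, 5), 4 * specificity_score(10, 5))
  # pluggable combination hook
  expect_equal(specificity_score(30, 10, combine = function(r, f) r), 3)
})

test_that("delivered volume is additive sphere volume", {
  expect_equal(delivered_volume(numeric(0)), 0)
  expect_equal(delivered_volume(100), 523598.8, tolerance = 1e-6)
  expect_equal(delivered_volume(c(60, 100)),
               delivered_volume(60) + delivered_volume(100))
})

test_that("Holm-Sidak adjustment matches the step-down definition", {
  hs <- holm_sidak_adjust(0.03)
  expect_equal(hs$adjusted, 0.03)
  hs2 <- holm_sidak_adjust(c(0.01, 0.04))
  expect_equal(hs2$adjusted, c(1 - 0.99^2, 0.04))
  p <- c(0.001, 0.2, 0.04, 0.5)
  hs3 <- holm_sidak_adjust(p, alpha = 0.05)
  expect_true(all(hs3$adjusted >= p))
  expect_equal(hs3$adjusted[order(p)], cummax(hs3$adjusted[order(p)]))
  expect_error(holm_sidak_adjust(c(0.1, 1.2)), "0, 1")
  # agreement with the brute-force definition on random vectors
  set.seed(61)
  for (k in 1:200) {
    m <- sample(1:6, 1)
    pv <- runif(m)
    expect_identical(holm_sidak_adjust(pv)$adjusted, holm_sidak_brute(pv))
  }
})

test_that("replicate t-test utility adjusts across conditions", {
  set.seed(71)
  a <- matrix(rnorm(40, 0), nrow = 4)
  b <- matrix(rnorm(40, c(3, 3, 0, 0)), nrow = 4)
  out <- replicate_t_tests(a, b)
  expect_equal(nrow(out), 4)
  expect_true(all(out$adjusted >= out$p))
})
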