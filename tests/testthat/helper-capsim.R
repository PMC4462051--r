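# Shared fixtures: small geometries and a fast configuration for
# whole-pipeline tests. Everything is generated in code.

small_geom <- function(...) vessel_geometry(...)

fast_config <- function(...) {
  simulation_config(mesh = list(nr = 20, nz = 100),
                    particles = list(n = 30),
                    time = list(total = 2e-3, record_every = 1), ...)
}

# Revolved volume of a closed (r, z) polyline by the divergence theorem:
# V = pi * sum (z_{k+1} - z_k) (r_k^2 + r_k r_{k+1} + r_{k+1}^2) / 3.
# Independent oracle for rbc_boundary_profile volumes.
revolved_volume <- function(prof) {
  r <- prof$r; z <- prof$z
  n <- length(r)
  abs(pi * sum(diff(z) * (r[-n]^2 + r[-n] * r[-1] + r[-1]^2) / 3))
}

# Brute-force Holm-Sidak step-down: literal transcription of the
# definition, kept independent of the implementation under test.
holm_sidak_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    a <- 1 - (1 - p[o[k]])^(m - k + 1)
    running <- max(running, a)
    adj[o[k]] <- running
  }
  adj
}

# Constant-velocity synthetic flow field on a small mesh (for advection
# arithmetic tests): nodal v_z = vz um/s everywhere, v_r = 0.
uniform_field <- function(geom, vz, nr = 8, nz = 16) {
  mesh <- build_mesh(geom, nr, nz)
  structure(list(v_r = rep(0, nrow(mesh$nodes)),
                 v_z = rep(vz, nrow(mesh$nodes)),
                 pressure = rep(0, nrow(mesh$nodes)),
                 mesh = mesh, mu = 1.2e-3, dp = 0, rbcs = list(),
                 rbc_velocity = 0, rbc_nodes = integer(0), rbc_force = 0),
            class = "flow_field")
}
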