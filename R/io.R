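#' Write a flow field as a legacy VTK file
#'
#' Exports the meridional mesh with nodal point data (`velocity` as a
#' 3-vector `(v_r, 0, v_z)` in um/s and `pressure` in Pa) in ASCII legacy
#' VTK, suitable for heat-map rendering.
#'
#' @param field A [solve_flow()] result.
#' @param file Output path (conventionally `.vtk`).
#' @return `file`, invisibly.
#' @export
write_vtk <- function(field, file) {
  mesh <- field$mesh
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "capsim axisymmetric flow field (r, z plane)",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.6g %.6g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 4L * ne), con)
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("5", ne), con)                       # VTK_TRIANGLE
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines("VECTORS velocity float", con)
  writeLines(sprintf("%.6g 0 %.6g", field$v_r, field$v_z), con)
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6g", field$pressure), con)
  invisible(file)
}

#' Write a trajectory array as CSV
#'
#' Long format: one row per (time, particle) with columns
#' `time, id, x, y, z, status`.
#'
#' @param traj Array (time, particle, 3) in nm.
#' @param times Times (s) for the first dimension.
#' @param file Output path.
#' @param status Optional final status per particle (recycled over time).
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(traj, times, file, status = NULL) {
  stopifnot(length(dim(traj)) == 3L)
  nt <- dim(traj)[1]; np <- dim(traj)[2]
  df <- data.frame(time = rep(times, each = np),
                   id = rep(seq_len(np), times = nt),
                   x = as.vector(t(traj[, , 1])),
                   y = as.vector(t(traj[, , 2])),
                   z = as.vector(t(traj[, , 3])),
                   status = if (is.null(status)) "free"
                            else rep(status, times = nt))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write run outputs to a directory
#'
#' Every run directory receives the configuration copy (`config.yaml`,
#' including the seed), a metrics summary (`metrics.json`), the event
#' ledger (`events.csv`), the trajectory (`trajectory.csv`, when recorded)
#' and the flow field (`flow.vtk`).
#'
#' @param result A [simulate_capillary()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg$output$dir <- NULL
  write_config(cfg, file.path(dir, "config.yaml"))
  write_metrics_json(c(result$summary, list(seed = result$config$seed)),
                     file.path(dir, "metrics.json"))
  utils::write.csv(result$ledger, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(result$trajectory))
    write_trajectory_csv(result$trajectory, result$times,
                         file.path(dir, "trajectory.csv"), result$status)
  write_vtk(result$field, file.path(dir, "flow.vtk"))
  invisible(dir)
}

#' Write a metrics list as JSON
#' @param metrics Named list of metric values.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_metrics_json <- function(metrics, file) {
  jsonlite::write_json(metrics, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(file)
}

#' Export red blood cell profiles as a CSV polyline table
#' @param rbcs List of [rbc_agent()].
#' @param file Output path.
#' @param n_points Points per face. Default 48.
#' @return `file`, invisibly.
#' @export
write_rbc_profiles_csv <- function(rbcs, file, n_points = 48) {
  rows <- lapply(seq_along(rbcs), function(i) {
    prof <- rbc_boundary_profile(rbcs[[i]], n_points)
    cbind(cell = i, prof)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
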