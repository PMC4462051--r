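#' Structured axisymmetric mesh of the vessel
#'
#' Triangulates the meridional rectangle (r, z) in [0, R] x [0, L] on a
#' structured grid, each cell split into two triangles. The structured layout
#' gives O(1) point location for velocity interpolation. Boundary edges carry
#' tags `wall` (r = R), `axis` (r = 0), `inlet` (z = 0) and `outlet` (z = L);
#' red blood cells are imposed later as nodal constraint sets.
#'
#' @param geom A [vessel_geometry()].
#' @param nr,nz Number of cells radially / axially.
#' @return An object of class `capsim_mesh` with fields `nodes` (N x 2
#'   matrix, nm), `elements` (Ne x 3 integer matrix, counter-clockwise),
#'   `boundary` (data.frame: node indices `a`, `b`, `tag`), `node_tag`
#'   (per-node: interior/wall/axis/inlet/outlet), and the grid descriptors
#'   `nr`, `nz`, `dr`, `dz`.
#' @export
build_mesh <- function(geom, nr = 40, nz = 200) {
  nr <- as.integer(nr); nz <- as.integer(nz)
  if (nr < 4 || nz < 4) stop("mesh must have at least 4x4 cells")
  R <- geom$radius; L <- geom$length
  dr <- R / nr; dz <- L / nz
  rs <- seq(0, R, length.out = nr + 1L)
  zs <- seq(0, L, length.out = nz + 1L)
  # node index: (i, j) -> i + (nr+1)*(j) + 1, i in 0..nr (radial), j in 0..nz
  nodes <- cbind(r = rep(rs, times = nz + 1L), z = rep(zs, each = nr + 1L))
  nid <- function(i, j) i + (nr + 1L) * j + 1L
  i <- rep(0L:(nr - 1L), times = nz)
  j <- rep(0L:(nz - 1L), each = nr)
  n00 <- nid(i, j); n10 <- nid(i + 1L, j)
  n01 <- nid(i, j + 1L); n11 <- nid(i + 1L, j + 1L)
  # lower triangle (n00, n10, n01), upper (n11, n01, n10); both CCW in (r, z)
  elements <- rbind(cbind(n00, n10, n01), cbind(n11, n01, n10))
  colnames(elements) <- NULL
  node_tag <- rep("interior", nrow(nodes))
  node_tag[nodes[, 1] == 0] <- "axis"
  node_tag[nodes[, 1] == R] <- "wall"
  inlet <- nodes[, 2] == 0 & node_tag == "interior"
  outlet <- nodes[, 2] == L & node_tag == "interior"
  node_tag[inlet] <- "inlet"
  node_tag[outlet] <- "outlet"
  boundary <- rbind(
    data.frame(a = nid(nr, 0L:(nz - 1L)), b = nid(nr, 1L:nz), tag = "wall"),
    data.frame(a = nid(0L, 0L:(nz - 1L)), b = nid(0L, 1L:nz), tag = "axis"),
    data.frame(a = nid(0L:(nr - 1L), 0L), b = nid(1L:nr, 0L), tag = "inlet"),
    data.frame(a = nid(0L:(nr - 1L), nz), b = nid(1L:nr, nz), tag = "outlet"))
  structure(list(nodes = nodes, elements = elements, boundary = boundary,
                 node_tag = node_tag, nr = nr, nz = nz, dr = dr, dz = dz,
                 geom = geom),
            class = "capsim_mesh")
}

#' @export
print.capsim_mesh <- function(x, ...) {
  cat(sprintf("<capsim_mesh> %d nodes, %d triangles (%d x %d cells)\n",
              nrow(x$nodes), nrow(x$elements), x$nr, x$nz))
  invisible(x)
}

#' Signed areas of all mesh triangles (nm^2)
#' @param mesh A [build_mesh()] result.
#' @return Numeric vector, positive for counter-clockwise elements.
#' @export
element_areas <- function(mesh) {
  el <- mesh$elements
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  p2 <- mesh$nodes[el[, 2], , drop = FALSE]
  p3 <- mesh$nodes[el[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Element centroids (nm)
#' @param mesh A [build_mesh()] result.
#' @return Ne x 2 matrix of (r, z) centroids.
#' @export
element_centroids <- function(mesh) {
  el <- mesh$elements
  (mesh$nodes[el[, 1], , drop = FALSE] +
   mesh$nodes[el[, 2], , drop = FALSE] +
   mesh$nodes[el[, 3], , drop = FALSE]) / 3
}

#' Export a mesh as plain CSV files
#' @param mesh A [build_mesh()] result.
#' @param prefix Output path prefix; writes `<prefix>_nodes.csv` and
#'   `<prefix>_elements.csv`.
#' @return The two file paths, invisibly.
#' @export
write_mesh_csv <- function(mesh, prefix) {
  fn <- paste0(prefix, "_nodes.csv")
  fe <- paste0(prefix, "_elements.csv")
  utils::write.csv(data.frame(r_nm = mesh$nodes[, 1], z_nm = mesh$nodes[, 2],
                              tag = mesh$node_tag), fn, row.names = FALSE)
  utils::write.csv(as.data.frame(mesh$elements), fe, row.names = FALSE)
  invisible(c(fn, fe))
}
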