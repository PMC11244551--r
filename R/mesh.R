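#' Triangulated surface mesh
#'
#' Container for a closed (or open) triangulated chamber surface as exported
#' by an electro-anatomical mapping system: vertex coordinates in millimetres
#' and triangles as vertex-index triples. Indices are 1-based inside R; the
#' on-disk container stores them 0-based (see [save_study()]).
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, three 1-based
#'   vertex indices per row.
#' @return An object of class `epm_mesh` with elements `vertices` and
#'   `triangles`.
#' @examples
#' m <- epm_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'               matrix(c(1L, 2L, 3L), 1))
#' triangle_areas(m)
#' @export
epm_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  triangles <- as.matrix(triangles)
  if (length(triangles) == 0L) triangles <- matrix(integer(0), 0L, 3L)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stop("triangle indices must be within 1..nrow(vertices)")
    degen <- triangles[, 1] == triangles[, 2] |
      triangles[, 2] == triangles[, 3] |
      triangles[, 1] == triangles[, 3]
    if (any(degen)) stop("triangles must not repeat a vertex")
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "epm_mesh")
}

#' @export
print.epm_mesh <- function(x, ...) {
  cat(sprintf("<epm_mesh> %d vertices, %d triangles, total area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), total_area(x)))
  invisible(x)
}

#' Per-triangle surface areas
#'
#' Area of each mesh triangle as half the magnitude of the edge cross
#' product. Degenerate (colinear) triangles get area 0 with a warning.
#'
#' @param mesh an [epm_mesh()].
#' @return Numeric vector of areas in mm^2, one per triangle.
#' @export
triangle_areas <- function(mesh) {
  stopifnot(inherits(mesh, "epm_mesh"))
  tri <- mesh$triangles
  if (nrow(tri) == 0L) return(numeric(0))
  a <- mesh$vertices[tri[, 1], , drop = FALSE]
  u <- mesh$vertices[tri[, 2], , drop = FALSE] - a
  v <- mesh$vertices[tri[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  areas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (any(areas == 0)) warning("mesh contains degenerate (zero-area) triangles")
  areas
}

#' Total mesh surface area
#'
#' @param mesh an [epm_mesh()].
#' @return Total surface area in mm^2.
#' @export
total_area <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(0)
  sum(triangle_areas(mesh))
}

#' Unique undirected edges of a mesh
#'
#' @param mesh an [epm_mesh()].
#' @return Two-column integer matrix of unique vertex-index pairs (i < j).
#' @export
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic of a mesh
#'
#' V - E + F; equals 2 for a closed surface of genus 0 (a topological
#' sphere), which is what the synthetic chamber generator produces.
#'
#' @param mesh an [epm_mesh()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$triangles)
}

# Weighted edge graph of the mesh (edge weight = Euclidean length), used for
# geodesic contour closure in ROI selection.
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::make_graph(t(e), n = nrow(mesh$vertices), directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

# Index of the nearest mesh vertex for each row of `positions`.
nearest_vertex <- function(positions, mesh) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  v <- mesh$vertices
  vv <- rowSums(v^2)
  idx <- integer(nrow(positions))
  for (i in seq_len(nrow(positions))) {
    d2 <- vv - 2 * as.numeric(v %*% positions[i, ])
    idx[i] <- which.min(d2)
  }
  idx
}
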