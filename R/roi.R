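#' Define a polygonal region of interest on the mesh
#'
#' The user supplies an ordered loop of mesh vertex IDs (as they would be
#' picked on a 3D map viewer). Consecutive picks are joined by the shortest
#' edge path over the mesh (geodesic over edges), closing the loop. The
#' resulting contour must split the closed surface into two components;
#' the interior is the component containing `interior_hint` if given,
#' otherwise the smaller-area component (ties go to the component holding
#' the lowest vertex ID). Contour vertices belong to the interior
#' (boundary-inclusive), and boundary triangles are assigned to the
#' interior when at least two of their three vertices are interior.
#' Selection order (clockwise vs anticlockwise) does not matter.
#'
#' @param mesh an [epm_mesh()].
#' @param contour_vertex_ids ordered vector of >= 3 distinct vertex IDs.
#' @param interior_hint optional vertex ID inside the intended region.
#' @param name label for the ROI.
#' @return An object of class `epm_roi`: list with `name`, `contour_input`,
#'   `contour` (full closed loop of vertex IDs), `interior_vertices` and
#'   `interior_triangles` (logical masks), `interior_hint`, and the `mesh`.
#' @export
define_roi <- function(mesh, contour_vertex_ids, interior_hint = NULL,
                       name = "roi") {
  ids <- as.integer(contour_vertex_ids)
  if (length(unique(ids)) < 3L) stop("at least 3 distinct contour vertices required")
  if (any(ids < 1L | ids > nrow(mesh$vertices))) stop("contour vertex ID out of range")
  g <- mesh_graph(mesh)
  loop <- integer(0)
  for (i in seq_along(ids)) {
    from <- ids[i]
    to <- ids[if (i == length(ids)) 1L else i + 1L]
    p <- igraph::shortest_paths(g, from, to, output = "vpath")$vpath[[1]]
    p <- as.integer(p)
    loop <- c(loop, p[-length(p)])
  }
  contour <- unique(loop)

  g2 <- igraph::delete_vertices(g, contour)
  remaining <- setdiff(seq_len(nrow(mesh$vertices)), contour)
  comp <- igraph::components(g2)
  if (comp$no < 2L)
    stop("degenerate contour: it does not separate the surface")
  membership <- integer(nrow(mesh$vertices))
  membership[remaining] <- comp$membership

  pick <- NULL
  if (!is.null(interior_hint)) {
    interior_hint <- as.integer(interior_hint)
    if (interior_hint %in% contour) {
      stop("interior_hint lies on the contour")
    }
    pick <- membership[interior_hint]
    if (pick == 0L) stop("interior_hint is not a mesh vertex off the contour")
  } else {
    areas <- triangle_areas(mesh)
    comp_area <- vapply(seq_len(comp$no), function(k) {
      inside <- membership == k
      inside[contour] <- TRUE
      sum(areas[rowSums(matrix(inside[mesh$triangles],
                               ncol = 3)) >= 2L])
    }, 1)
    pick <- which(comp_area == min(comp_area))
    if (length(pick) > 1L) {   # tie: component containing the lowest vertex ID
      low <- vapply(pick, function(k) min(which(membership == k)), 1L)
      pick <- pick[which.min(low)]
    }
  }

  interior_vertices <- membership == pick
  interior_vertices[contour] <- TRUE
  interior_triangles <- rowSums(matrix(interior_vertices[mesh$triangles],
                                       ncol = 3)) >= 2L
  structure(list(name = name,
                 contour_input = ids,
                 contour = contour,
                 interior_vertices = interior_vertices,
                 interior_triangles = interior_triangles,
                 interior_hint = interior_hint,
                 mesh = mesh),
            class = "epm_roi")
}

#' @export
print.epm_roi <- function(x, ...) {
  cat(sprintf("<epm_roi> '%s': %d contour vertices, %d interior vertices, %.1f mm^2\n",
              x$name, length(x$contour), sum(x$interior_vertices),
              roi_area(x)))
  invisible(x)
}

#' Interior surface area of a ROI
#' @param roi an [define_roi()] result.
#' @return Area in mm^2 of the interior triangles.
#' @export
roi_area <- function(roi) {
  sum(triangle_areas(roi$mesh)[roi$interior_triangles])
}

#' Which electro-anatomical points fall inside a ROI
#'
#' A point is inside the region when its nearest mesh vertex is an
#' interior vertex (contour vertices included), mirroring how the mapping
#' workflow compares point coordinates with the selected vertices.
#'
#' @param roi an [define_roi()] result.
#' @param study an [epm_study()], or a P x 3 matrix of surface positions.
#' @return Logical vector, one entry per point.
#' @export
roi_membership <- function(roi, study) {
  pos <- if (inherits(study, "epm_study")) study$surface_positions else as_xyz(study)
  if (nrow(pos) == 0L) return(logical(0))
  roi$interior_vertices[nearest_vertex(pos, roi$mesh)]
}

#' Re-interpolate a feature inside a ROI only
#'
#' Re-runs the interpolation restricted to the region: only the points
#' inside the ROI contribute, and only interior vertices receive values
#' (exterior vertices are missing). This is how a region is re-mapped
#' after selection so that exterior samples cannot bleed into it.
#'
#' @param study an [epm_study()].
#' @param roi an [define_roi()] result (on the study mesh).
#' @param point_values per-point feature values for the study.
#' @param method,max_distance,name passed to [interpolate_feature()].
#' @return An `epm_feature_map` whose field is `NA` outside the ROI.
#' @export
restrict_and_reinterpolate <- function(study, roi, point_values,
                                       method = "nearest",
                                       max_distance = NULL, name = "feature") {
  inside <- roi_membership(roi, study)
  use <- inside & !is.na(point_values)
  if (!any(use)) stop("no valid points inside the ROI")
  fm <- interpolate_feature(study$surface_positions[use, , drop = FALSE],
                            point_values[use], study$mesh,
                            method = method, max_distance = max_distance,
                            name = name)
  fm$vertex_field[!roi$interior_vertices] <- NA_real_
  fm$point_values <- ifelse(use, point_values, NA_real_)
  fm
}

#' Persist a ROI definition as JSON
#'
#' Only the reproducible inputs are stored (name, picked contour vertex
#' IDs, interior hint); vertex IDs are written 0-based, matching the
#' native HDF5 container convention.
#'
#' @param roi an [define_roi()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_roi <- function(roi, path) {
  obj <- list(name = roi$name,
              contour_vertex_ids = roi$contour_input - 1L,
              interior_hint = if (is.null(roi$interior_hint)) NULL
                              else roi$interior_hint - 1L)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a ROI definition from JSON and rebuild it on a mesh
#'
#' @param path JSON file written by [save_roi()].
#' @param mesh the [epm_mesh()] the vertex IDs refer to.
#' @return An `epm_roi`.
#' @export
load_roi <- function(path, mesh) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  define_roi(mesh, as.integer(obj$contour_vertex_ids) + 1L,
             interior_hint = if (is.null(obj$interior_hint)) NULL
                             else as.integer(obj$interior_hint) + 1L,
             name = obj$name)
}
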