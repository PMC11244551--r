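#' Interpolate scattered point values onto mesh vertices
#'
#' Builds a continuous parametric map from per-point measurements: every
#' mesh vertex is assigned a value from the sampled electro-anatomical
#' points. The default (and recommended) method is nearest-neighbour
#' assignment -- discontinuous but the most accurate in terms of error
#' between interpolated and measured data for this kind of map; an
#' inverse-distance-weighted `"idw"` method is provided as the smooth
#' fallback. Sample positions should be the surface projections of the
#' acquisition points.
#'
#' @param point_positions P x 3 matrix of sample coordinates (mm).
#' @param point_values length-P numeric values (NA samples are dropped).
#' @param mesh an [epm_mesh()].
#' @param method `"nearest"` (default) or `"idw"`. `"linear"`
#'   (barycentric within a Delaunay tessellation of the samples) is part of
#'   the method contract but requires a 3-D Delaunay backend that is not
#'   available; requesting it is an error.
#' @param max_distance vertices farther than this from every sample are
#'   left missing (`NA`); `NULL` (default) fills the whole surface.
#' @param name feature name stored in the map.
#' @return An object of class `epm_feature_map`: list with `name`,
#'   `point_values`, `vertex_field` (length = vertex count, `NA` =
#'   missing), `method`, `max_distance`.
#' @export
interpolate_feature <- function(point_positions, point_values, mesh,
                                method = c("nearest", "idw", "linear"),
                                max_distance = NULL, name = "feature") {
  method <- match.arg(method)
  if (method == "linear")
    stop("method 'linear' requires a 3-D Delaunay tessellation backend, ",
         "which is not available; use 'nearest' (default) or 'idw'")
  point_positions <- as_xyz(point_positions)
  point_values <- as.numeric(point_values)
  stopifnot(nrow(point_positions) == length(point_values))
  ok <- !is.na(point_values) & is.finite(rowSums(point_positions))
  if (!any(ok)) stop("no valid sample points to interpolate from")
  p <- point_positions[ok, , drop = FALSE]
  v <- point_values[ok]

  verts <- mesh$vertices
  d2 <- dist2_matrix(verts, p)                    # N x P squared distances
  nn <- max.col(-d2, ties.method = "first")       # ties -> lowest sample index
  dmin <- sqrt(d2[cbind(seq_len(nrow(verts)), nn)])

  field <- if (method == "nearest") {
    v[nn]
  } else {
    w <- 1 / pmax(d2, 1e-12)
    out <- as.numeric(w %*% v) / rowSums(w)
    exact <- dmin < 1e-9
    out[exact] <- v[nn[exact]]
    out
  }
  if (!is.null(max_distance)) field[dmin > max_distance] <- NA_real_

  structure(list(name = name,
                 point_values = point_values,
                 vertex_field = field,
                 method = method,
                 max_distance = max_distance),
            class = "epm_feature_map")
}

# Squared Euclidean distances between rows of a (n x 3) and rows of b (m x 3).
dist2_matrix <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' @export
print.epm_feature_map <- function(x, ...) {
  miss <- sum(is.na(x$vertex_field))
  cat(sprintf("<epm_feature_map> '%s' (%s): %d samples -> %d vertices (%d missing)\n",
              x$name, x$method, sum(!is.na(x$point_values)),
              length(x$vertex_field), miss))
  invisible(x)
}

#' Export a mesh and its vertex fields as legacy VTK PolyData
#'
#' Writes an ASCII legacy `.vtk` PolyData file with one point-data array
#' per feature map (missing values encoded as NaN), readable by standard
#' VTK-based viewers (ParaView etc.). Values are printed with 17
#' significant digits so a read-back reproduces them bit-for-bit.
#'
#' @param mesh an [epm_mesh()].
#' @param feature_maps list of [interpolate_feature()] results (possibly
#'   empty for a geometry-only file); a bare numeric vector of length =
#'   vertex count is also accepted and named by its list name.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(mesh, feature_maps = list(), path) {
  if (inherits(feature_maps, "epm_feature_map"))
    feature_maps <- list(feature_maps)
  fields <- list()
  for (i in seq_along(feature_maps)) {
    fm <- feature_maps[[i]]
    if (inherits(fm, "epm_feature_map")) {
      fields[[fm$name]] <- fm$vertex_field
    } else {
      nm <- names(feature_maps)[i]
      if (is.null(nm) || nm == "") nm <- paste0("field_", i)
      fields[[nm]] <- as.numeric(fm)
    }
  }
  nv <- nrow(mesh$vertices)
  for (f in fields) if (length(f) != nv)
    stop("field length must equal the vertex count")
  num <- function(x) {
    s <- sprintf("%.17g", x)
    s[is.na(x)] <- "nan"
    s
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "epmap surface map", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(num(r), collapse = " ")),
             con)
  nt <- nrow(mesh$triangles)
  writeLines(sprintf("POLYGONS %d %d", nt, 4L * nt), con)
  if (nt > 0)
    writeLines(apply(mesh$triangles - 1L, 1,
                     function(r) paste(c(3L, r), collapse = " ")), con)
  if (length(fields) > 0) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    writeLines(sprintf("FIELD maps %d", length(fields)), con)
    for (nm in names(fields)) {
      writeLines(sprintf("%s 1 %d double", nm, nv), con)
      writeLines(paste(num(fields[[nm]]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read back a legacy VTK PolyData file written by [export_vtk()]
#'
#' @param path file path.
#' @return List with `mesh` (an [epm_mesh()]) and `fields` (named list of
#'   vertex vectors, NaN restored as `NA`).
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS ", ln)[1]
  nv <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  verts <- matrix(as.numeric(unlist(strsplit(ln[ip + seq_len(nv)], " "))),
                  nv, 3, byrow = TRUE)
  it <- grep("^POLYGONS ", ln)[1]
  nt <- as.integer(strsplit(ln[it], " ")[[1]][2])
  tri <- if (nt > 0) {
    m <- matrix(as.integer(unlist(strsplit(ln[it + seq_len(nt)], " "))),
                nt, 4, byrow = TRUE)
    m[, 2:4] + 1L
  } else matrix(integer(0), 0, 3)
  fields <- list()
  ifd <- grep("^FIELD ", ln)
  if (length(ifd) == 1) {
    k <- as.integer(strsplit(ln[ifd], " ")[[1]][3])
    pos <- ifd + 1L
    for (j in seq_len(k)) {
      hdr <- strsplit(ln[pos], " ")[[1]]
      vals <- as.numeric(strsplit(ln[pos + 1L], " ")[[1]])
      vals[is.nan(vals)] <- NA_real_
      fields[[hdr[1]]] <- vals
      pos <- pos + 2L
    }
  }
  list(mesh = epm_mesh(verts, tri), fields = fields)
}
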