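#' Project points onto a triangulated surface
#'
#' Finds, for each query point, the closest point lying on the mesh
#' (considering triangle faces, edges and vertices), replicating how an
#' electro-anatomical mapping system stores surface-projected acquisition
#' coordinates alongside the raw catheter coordinates.
#'
#' @param positions n x 3 matrix of query coordinates (mm).
#' @param mesh an [epm_mesh()] with at least one triangle.
#' @return n x 3 matrix of surface coordinates with attributes `distance`
#'   (mm to the surface) and `triangle` (index of the closest triangle).
#' @export
project_to_surface <- function(positions, mesh) {
  stopifnot(inherits(mesh, "epm_mesh"))
  if (nrow(mesh$triangles) == 0L) stop("mesh has no triangles")
  positions <- as_xyz(positions)
  tri <- mesh$triangles
  A <- mesh$vertices[tri[, 1], , drop = FALSE]
  B <- mesh$vertices[tri[, 2], , drop = FALSE]
  C <- mesh$vertices[tri[, 3], , drop = FALSE]
  out <- matrix(NA_real_, nrow(positions), 3L)
  dist <- numeric(nrow(positions))
  tidx <- integer(nrow(positions))
  for (i in seq_len(nrow(positions))) {
    cp <- closest_point_triangles(positions[i, ], A, B, C)
    d2 <- rowSums((cp - matrix(positions[i, ], nrow(cp), 3, byrow = TRUE))^2)
    j <- which.min(d2)
    out[i, ] <- cp[j, ]
    dist[i] <- sqrt(d2[j])
    tidx[i] <- j
  }
  attr(out, "distance") <- dist
  attr(out, "triangle") <- tidx
  out
}

# Closest point to p on each triangle (A[i,], B[i,], C[i,]); vectorised
# Voronoi-region classification (Ericson, Real-Time Collision Detection).
closest_point_triangles <- function(p, A, B, C) {
  n <- nrow(A)
  P <- matrix(p, n, 3, byrow = TRUE)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  res <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set <- function(mask, value) {
    mask <- mask & !done
    res[mask, ] <<- value[mask, , drop = FALSE]
    done[mask] <<- TRUE
  }
  set(d1 <= 0 & d2 <= 0, A)                                   # vertex A
  set(d3 >= 0 & d4 <= d3, B)                                  # vertex B
  set(d6 >= 0 & d5 <= d6, C)                                  # vertex C
  v <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * v)                # edge AB
  w <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * w)                # edge AC
  w2 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * w2) # edge BC
  denom <- 1 / (va + vb + vc)
  vi <- vb * denom; wi <- vc * denom
  set(rep(TRUE, n), A + ab * vi + ac * wi)                    # face interior

  # Degenerate triangles can yield non-finite interior solutions; fall back
  # to the best of the three vertices.
  bad <- which(!is.finite(rowSums(res)))
  for (i in bad) {
    cand <- rbind(A[i, ], B[i, ], C[i, ])
    d2c <- rowSums((cand - matrix(p, 3, 3, byrow = TRUE))^2)
    res[i, ] <- cand[which.min(d2c), ]
  }
  res
}
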