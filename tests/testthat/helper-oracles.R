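# Independent oracles and small fixture builders. Oracles are deliberately
# written as plain loops / closed forms so they share no code with the
# implementation paths they check.

# --- meshes -----------------------------------------------------------------

# Unit-cube surface: 8 vertices, 12 triangles, total area 6.
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  epm_mesh(v, tri)
}

# Flat rectangular strip in the z = 0 plane: `n` unit squares in a row,
# each split into two triangles.
strip_mesh <- function(n = 4) {
  v <- cbind(rep(0:n, each = 2), rep(c(0, 1), n + 1), 0)
  tri <- do.call(rbind, lapply(seq_len(n) - 1L, function(i)
    rbind(c(1, 3, 2) + 2L * i, c(2, 3, 4) + 2L * i)))
  epm_mesh(v, tri)
}

# Planar square grid mesh on [0, n] x [0, n], z = 0.
grid_mesh <- function(n = 6) {
  g <- as.matrix(expand.grid(x = 0:n, y = 0:n))
  v <- cbind(g, 0)
  id <- function(i, j) i + (n + 1L) * (j - 1L)
  tri <- do.call(rbind, lapply(seq_len(n), function(j)
    do.call(rbind, lapply(seq_len(n), function(i)
      rbind(c(id(i, j), id(i + 1, j), id(i, j + 1)),
            c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))))))
  epm_mesh(v, tri)
}

# --- oracles ----------------------------------------------------------------

# O(N*P) double-loop nearest-sample assignment with lowest-index ties.
oracle_nearest_interp <- function(vertices, points, values) {
  out <- numeric(nrow(vertices))
  for (i in seq_len(nrow(vertices))) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(nrow(points))) {
      d <- sum((vertices[i, ] - points[j, ])^2)
      if (d < best - 1e-15) { best <- d; bj <- j }
    }
    out[i] <- values[bj]
  }
  out
}

# O(n^2) nearest-pre-point pairing oracle (default mode).
oracle_pair <- function(pre, post, threshold) {
  res <- NULL
  for (i in seq_len(nrow(post))) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(nrow(pre))) {
      d <- sqrt(sum((post[i, ] - pre[j, ])^2))
      if (d < best - 1e-12) { best <- d; bj <- j }
    }
    if (best <= threshold)
      res <- rbind(res, data.frame(post_idx = i, pre_idx = bj,
                                   distance_mm = best))
  }
  if (is.null(res)) data.frame(post_idx = integer(0), pre_idx = integer(0),
                               distance_mm = numeric(0))
  else res
}

# Greedy one-to-one oracle: repeatedly take the global minimum pair.
oracle_pair_unique <- function(pre, post, threshold) {
  d <- matrix(Inf, nrow(post), nrow(pre))
  for (i in seq_len(nrow(post)))
    for (j in seq_len(nrow(pre)))
      d[i, j] <- sqrt(sum((post[i, ] - pre[j, ])^2))
  res <- NULL
  while (TRUE) {
    mn <- min(d)
    if (!is.finite(mn) || mn > threshold) break
    ij <- which(d == mn, arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    res <- rbind(res, data.frame(post_idx = ij[1], pre_idx = ij[2],
                                 distance_mm = mn))
    d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
  }
  if (is.null(res)) return(data.frame(post_idx = integer(0),
                                      pre_idx = integer(0),
                                      distance_mm = numeric(0)))
  res <- res[order(res$post_idx), ]
  rownames(res) <- NULL
  res
}

# 2-D winding-number point-in-polygon test (polygon given as closed order).
oracle_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  wn <- 0
  for (k in seq_len(n)) {
    x1 <- poly_x[k]; y1 <- poly_y[k]
    x2 <- poly_x[k %% n + 1]; y2 <- poly_y[k %% n + 1]
    if (y1 <= py) {
      if (y2 > py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0)
        wn <- wn + 1
    } else {
      if (y2 <= py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0)
        wn <- wn - 1
    }
  }
  wn != 0
}

# Brute-force distance from p to a triangle: dense barycentric sampling.
oracle_triangle_distance <- function(p, a, b, c3, n = 200) {
  g <- seq(0, 1, length.out = n)
  best <- Inf
  for (u in g) {
    vmax <- 1 - u
    for (v in seq(0, vmax, length.out = max(2, ceiling(n * vmax)))) {
      q <- a + u * (b - a) + v * (c3 - a)
      best <- min(best, sqrt(sum((p - q)^2)))
    }
  }
  best
}

# Well-separated vertex picks around the z ~ 0 equator of a closed mesh,
# for building ROIs that split it into two hemispheres.
equator_picks <- function(mesh, k = 6, band = NULL) {
  if (is.null(band)) band <- diff(range(mesh$vertices[, 3])) / 12
  near <- which(abs(mesh$vertices[, 3]) < band)
  ang <- atan2(mesh$vertices[near, 2], mesh$vertices[near, 1])
  near[order(ang)][round(seq(1, length(near), length.out = k + 1))[1:k]]
}

# --- study fixtures ---------------------------------------------------------

# Small fast study: short timeline keeps the HDF5 round-trip suite quick.
tiny_study <- function(n_points = 5, seed = 1, noise_sd = 0, ...) {
  mesh <- make_rv_mesh(1, seed = seed)
  make_study(mesh, n_points, at_field = 20, ari_field = 250,
             jel_field = 0.8, reference_annotation = 300,
             duration_ms = 1000, noise_sd = noise_sd, seed = seed, ...)
}

# Spatially varying fields over a mesh, inside the generator's validity
# domain (activation at least 12 ms before the study J-point).
varying_fields <- function(mesh) {
  rg <- apply(mesh$vertices, 2, range)
  list(at = function(p) 5 + 40 * (p[, 3] - rg[1, 3]) / diff(rg[, 3]),
       ari = function(p) 200 + 120 * (p[, 1] - rg[1, 1]) / diff(rg[, 1]),
       jel = function(p) 0.2 + 1.3 * (p[, 2] - rg[1, 2]) / diff(rg[, 2]))
}
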