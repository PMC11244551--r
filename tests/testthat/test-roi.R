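# An icosphere-based closed mesh with an equatorial contour splits into two
# hemispheres; a planar grid with a square contour is checkable against a
# 2-D winding-number oracle. (equator_picks lives in helper-oracles.R.)

test_that("equatorial contour yields a hemisphere; orientation-free", {
  m <- make_rv_mesh(2, bulge_amplitude = 0, seed = 50)
  picks <- equator_picks(m)
  roi <- define_roi(m, picks)
  frac <- roi_area(roi) / total_area(m)
  expect_gt(frac, 0.3); expect_lt(frac, 0.7)
  # reversed pick order gives the identical interior
  roi_rev <- define_roi(m, rev(picks))
  expect_identical(roi$interior_vertices, roi_rev$interior_vertices)
  # hint flips the selection to the complement side
  out_v <- which(!roi$interior_vertices)[1]
  roi_out <- define_roi(m, picks, interior_hint = out_v)
  expect_true(all(!roi$interior_vertices[setdiff(which(roi_out$interior_vertices),
                                                 roi$contour)]))
})

test_that("degenerate contours are rejected", {
  m <- make_rv_mesh(1, seed = 51)
  expect_error(define_roi(m, c(1, 2)), "3 distinct")
  # three mutually adjacent vertices of one triangle do not separate a sphere
  tri <- m$triangles[1, ]
  expect_error(define_roi(m, tri), "degenerate")
})

test_that("interior + exterior areas partition the total exactly", {
  m <- make_rv_mesh(2, seed = 52)
  roi <- define_roi(m, equator_picks(m))
  ext <- sum(triangle_areas(m)[!roi$interior_triangles])
  expect_equal(roi_area(roi) + ext, total_area(m), tolerance = 1e-12)
})

test_that("planar membership equals the 2-D winding-number oracle", {
  m <- grid_mesh(6)
  # square contour through grid vertices (1,1) .. (5,5)
  id <- function(i, j) (i + 1) + 7 * j
  picks <- c(id(1, 1), id(5, 1), id(5, 5), id(1, 5))
  roi <- define_roi(m, picks, interior_hint = id(3, 3))
  set.seed(53)
  pts <- cbind(runif(150, 0.2, 5.8), runif(150, 0.2, 5.8), 0)
  # keep points more than half a cell away from the contour lines so
  # vertex-snapping and the polygon test agree on unambiguous cases
  dd <- pmin(abs(pts[, 1] - 1), abs(pts[, 1] - 5),
             abs(pts[, 2] - 1), abs(pts[, 2] - 5))
  pts <- pts[dd > 0.55, , drop = FALSE]
  got <- roi_membership(roi, pts)
  want <- vapply(seq_len(nrow(pts)), function(i)
    oracle_in_polygon(pts[i, 1], pts[i, 2],
                      c(1, 5, 5, 1), c(1, 1, 5, 5)), TRUE)
  expect_identical(got, want)
  # a point exactly on a contour vertex is inside (boundary inclusive)
  expect_true(roi_membership(roi, rbind(c(1, 1, 0))))
})

test_that("whole-surface ROI keeps every point and reproduces global maps", {
  sim <- tiny_study(20, seed = 54)
  s <- sim$study
  m <- s$mesh
  # contour = small triangle patch; interior hint on the far side makes the
  # interior cover almost the whole surface
  picks <- equator_picks(m, k = 5)
  far <- which.max(m$vertices[, 3])
  roi <- define_roi(m, picks, interior_hint = far)
  vals <- rnorm(20)
  inside <- roi_membership(roi, s)
  fm_roi <- restrict_and_reinterpolate(s, roi, vals)
  fm_all <- interpolate_feature(s$surface_positions[inside, , drop = FALSE],
                                vals[inside], m)
  iv <- roi$interior_vertices
  expect_equal(fm_roi$vertex_field[iv], fm_all$vertex_field[iv])
  expect_true(all(is.na(fm_roi$vertex_field[!iv])))
})

test_that("ROI re-interpolation ignores exterior outliers entirely", {
  m <- make_rv_mesh(2, bulge_amplitude = 0, seed = 55)
  set.seed(56)
  pts <- sample_surface_points(m, 40)
  sim_study <- epm_study(m, pts, matrix(0, 40, 600), surface_positions = pts,
                         ecg = list(), sampling_rate = 1000,
                         reference_annotation = 300, woi = c(-100, 100))
  roi <- define_roi(m, equator_picks(m))
  inside <- roi_membership(roi, sim_study)
  expect_true(sum(inside) >= 2 && !all(inside))
  vals <- rnorm(40)
  vals[!inside] <- 1e6                     # exterior outliers
  fm <- restrict_and_reinterpolate(sim_study, roi, vals)
  expect_lt(max(abs(fm$vertex_field), na.rm = TRUE), 1e5)
  expect_error(restrict_and_reinterpolate(sim_study, roi, rep(NA_real_, 40)),
               "no valid")
})

test_that("ROI JSON persistence round-trips the definition", {
  m <- make_rv_mesh(1, seed = 57)
  roi <- define_roi(m, equator_picks(m, 4), name = "rvot")
  f <- withr::local_tempfile(fileext = ".json")
  save_roi(roi, f)
  back <- load_roi(f, m)
  expect_identical(back$interior_vertices, roi$interior_vertices)
  expect_identical(back$name, "rvot")
})
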