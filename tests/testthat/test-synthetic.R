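test_that("mesh generator: base case, determinism, topology", {
  m0 <- make_rv_mesh(0, bulge_amplitude = 0, seed = 1)
  expect_identical(nrow(m0$triangles), 20L)
  expect_identical(nrow(m0$vertices), 12L)
  m1 <- make_rv_mesh(2, seed = 9)
  m2 <- make_rv_mesh(2, seed = 9)
  expect_identical(m1$vertices, m2$vertices)
  expect_false(identical(m1$vertices, make_rv_mesh(2, seed = 10)$vertices))
  expect_true(length(attr(m1, "rvot_vertices")) > 0)
})

test_that("electrogram fiducials sit where they were placed", {
  fs <- 1000
  u <- make_unipolar_egm(fs = fs, ref_ms = 2000, at_offset_ms = 20,
                         ari_ms = 250, jel_mv = 1.0)
  # discrete differentiation, no shared code with the extractors
  d <- diff(u) * fs / 1000
  dep <- which.min(d[1901:2101]) + 1900
  expect_lte(abs(dep - 2021), 1)
  tseg <- d[(dep + 120):(dep + 450)]
  expect_lte(abs(which.max(tseg) + 119 - 250), 1)
  # J-elevation by construction: value at the J-point, baseline zero
  fid <- attr(u, "fiducials")
  j <- round(fid$t_j_ms) + 1
  expect_equal(u[j] - median(u[1:1800]), 1.0, tolerance = 1e-9)
  # determinism under seed, with noise
  a <- make_unipolar_egm(noise_sd_mv = 0.05, seed = 33)
  b <- make_unipolar_egm(noise_sd_mv = 0.05, seed = 33)
  expect_identical(a, b)
  expect_error(make_unipolar_egm(ari_ms = 900, duration_ms = 2500), "outside")
})

test_that("constant-field study recovers its constants through the pipeline", {
  sim <- tiny_study(12, seed = 5)
  f <- extract_features(sim$study)
  expect_equal(f$at_ms, rep(20, 12), tolerance = 1e-9)
  expect_equal(f$ari_ms, rep(250, 12), tolerance = 1e-9)
  expect_equal(f$uni_jel_mv, rep(0.8, 12), tolerance = 1e-6)
  expect_true(all(f$quality))
})

test_that("single-point studies and determinism", {
  s1 <- tiny_study(1, seed = 2)
  expect_identical(n_points(s1$study), 1L)
  s2 <- tiny_study(4, seed = 8)
  s3 <- tiny_study(4, seed = 8)
  expect_identical(s2$study$unipolar, s3$study$unipolar)
  expect_identical(s2$study$positions, s3$study$positions)
  expect_error(make_study(make_rv_mesh(1), 0), "n_points")
})

test_that("pre/post generator: identity limit and recorded deltas", {
  sim <- tiny_study(15, seed = 6)
  pp <- make_pre_post(sim, delta_fields = list(), dropout = 0, jitter_mm = 0,
                      seed = 3)
  expect_identical(n_points(pp$post), 15L)
  expect_equal(pp$post$unipolar, sim$study$unipolar, tolerance = 1e-12)
  expect_equal(pp$post$surface_positions, sim$study$surface_positions)

  pp2 <- make_pre_post(sim, delta_fields = list(jel = 0.9), dropout = 0.3,
                       jitter_mm = 0, seed = 4)
  expect_equal(pp2$truth$post$deltas$jel,
               rep(0.9, n_points(pp2$post)), tolerance = 1e-12)
  expect_identical(pp2$truth$post$pre_index,
                   which(seq_len(15) %in% pp2$truth$post$pre_index))
})

test_that("dropout produces binomial point loss (quick check)", {
  sim <- tiny_study(200, seed = 13)
  counts <- vapply(1:30, function(sd)
    n_points(make_pre_post(sim, dropout = 0.36, jitter_mm = 0,
                           seed = sd)$post), 1L)
  # mean within 4 SE of 200 * 0.64 for this quick version
  se <- sqrt(200 * 0.36 * 0.64 / 30)
  expect_lt(abs(mean(counts) - 128), 4 * se)
})
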