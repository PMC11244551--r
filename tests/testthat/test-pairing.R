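test_that("identical point sets pair to themselves at distance 0", {
  set.seed(60)
  p <- matrix(rnorm(45), 15, 3)
  pr <- pair_points(p, p)
  expect_identical(pr$post_idx, 1:15)
  expect_identical(pr$pre_idx, 1:15)
  expect_equal(pr$distance_mm, rep(0, 15))
})

test_that("distances strictly above the threshold are excluded, at it kept", {
  pre <- rbind(c(0, 0, 0))
  expect_identical(nrow(pair_points(pre, rbind(c(6, 0, 0)))), 0L)
  at5 <- pair_points(pre, rbind(c(5, 0, 0)))
  expect_identical(nrow(at5), 1L)
  expect_equal(at5$distance_mm, 5)
  expect_error(pair_points(matrix(numeric(0), 0, 3), pre), "non-empty")
})

test_that("both modes match the O(n^2) oracles on random clouds", {
  set.seed(61)
  for (rep in 1:10) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    pre <- matrix(rnorm(3 * n1, sd = 4), n1, 3)
    post <- matrix(rnorm(3 * n2, sd = 4), n2, 3)
    got <- pair_points(pre, post)
    want <- oracle_pair(pre, post, 5)
    expect_equal(got$post_idx, want$post_idx)
    expect_equal(got$pre_idx, want$pre_idx)
    expect_equal(got$distance_mm, want$distance_mm)
    gotu <- pair_points(pre, post, unique = TRUE)
    wantu <- oracle_pair_unique(pre, post, 5)
    expect_equal(gotu$post_idx, wantu$post_idx)
    expect_equal(gotu$pre_idx, wantu$pre_idx)
  }
})

test_that("unique mode: greedy distances non-decreasing, counts bounded", {
  set.seed(62)
  pre <- matrix(rnorm(90), 30, 3)
  post <- pre[sample(30, 20), ] + matrix(rnorm(60, sd = 0.3), 20, 3)
  pr <- pair_points(pre, post, unique = TRUE)
  expect_true(all(diff(attr(pr, "selection_distances")) >= 0))
  expect_lte(nrow(pr), 20)
  expect_false(any(duplicated(pr$pre_idx)))
  expect_false(any(duplicated(pr$post_idx)))
  prd <- pair_points(pre, post)
  expect_lte(nrow(prd), 20)
})

test_that("pairing is invariant under joint rigid transformation", {
  set.seed(63)
  pre <- matrix(rnorm(60), 20, 3)
  post <- pre + matrix(rnorm(60, sd = 0.5), 20, 3)
  base <- pair_points(pre, post)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mv <- function(x) x %*% R + matrix(c(1, 2, 3), nrow(x), 3, byrow = TRUE)
  moved <- pair_points(mv(pre), mv(post))
  expect_identical(moved$post_idx, base$post_idx)
  expect_identical(moved$pre_idx, base$pre_idx)
  expect_equal(moved$distance_mm, base$distance_mm, tolerance = 1e-9)
})

test_that("delta features: zeros, uniform shift, quality-dropped pairs", {
  sim <- tiny_study(25, seed = 64)
  fpre <- extract_features(sim$study)
  # identical features -> all deltas zero, map identically zero
  pairs <- pair_points(sim$study$surface_positions,
                       sim$study$surface_positions)
  d0 <- delta_features(fpre, fpre, pairs, post_study = sim$study)
  expect_equal(d0$deltas$delta_uni_jel_mv, rep(0, 25))
  expect_equal(d0$maps$delta_uni_jel_mv$vertex_field,
               rep(0, nrow(sim$study$mesh$vertices)))

  # uniform +0.9 mV shift, no dropout/jitter/noise: every delta exact
  pp <- make_pre_post(sim, delta_fields = list(jel = 0.9), dropout = 0.2,
                      jitter_mm = 0, seed = 65)
  fpost <- extract_features(pp$post)
  pr <- pair_points(pp$pre$surface_positions, pp$post$surface_positions)
  d <- delta_features(fpre, fpost, pr)
  expect_equal(d$deltas$delta_uni_jel_mv,
               rep(0.9, nrow(d$deltas)), tolerance = 1e-6)

  # a rejected post point drops its pair with a logged count
  fpost_bad <- fpost
  fpost_bad$quality[1] <- FALSE
  expect_message(d2 <- delta_features(fpre, fpost_bad, pr), "1 pair")
  expect_identical(nrow(d2$deltas), nrow(d$deltas) - 1L)
  expect_identical(attr(d2$deltas, "n_rejected"), 1L)
  expect_error(delta_features(fpre, fpost, pr, feature_names = "nope"),
               "absent")
})
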