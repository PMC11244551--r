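# Constructed ECG whose QRS offset is exactly at a known sample: linear
# S-wave recovery ends at `offset`, flat afterwards.
constructed_qrs <- function(offset = 2041, fs = 1000, n = 3000) {
  tt <- seq_len(n)
  x <- numeric(n)
  r0 <- offset - 60
  x <- x + 1.2 * exp(-(tt - (r0 + 15))^2 / (2 * 5^2))   # R wave
  nadir <- r0 + 30
  x <- x - 1.5 * exp(-(tt - nadir)^2 / (2 * 4^2))        # S wave
  ramp <- tt > nadir + 6 & tt <= offset                  # linear recovery
  x[ramp] <- x[ramp] - 0.4 * (offset - tt[ramp]) / (offset - nadir - 6)
  x
}

test_that("J-point detector finds a constructed QRS offset", {
  x <- constructed_qrs(2041)
  jp <- detect_jpoint(x, 1000)
  expect_lte(abs(jp - 2041), 5)
  expect_error(detect_jpoint(numeric(3000), 1000), "no QRS")
  # translation equivariance
  sh <- c(numeric(50), x)[1:3000]
  expect_identical(detect_jpoint(sh, 1000), jp + 50L)
})

test_that("median J-point uses the lower-median rule", {
  expect_identical(median_jpoint(c(100L, 102L, 104L)), 102L)
  expect_identical(median_jpoint(100L), 100L)
  expect_identical(median_jpoint(c(100L, 104L)), 100L)
  expect_error(median_jpoint(integer(0)), "no J-points")
})

test_that("Uni-JEl is the J-point value minus the baseline median", {
  x <- rep(0.5, 3000)
  x[2065] <- 2.0
  expect_equal(compute_uni_jel(x, 2065, 1000), 1.5)
  expect_equal(compute_uni_jel(numeric(3000), 2065, 1000), 0)
  expect_error(compute_uni_jel(x, 5000, 1000), "outside")
  expect_error(compute_uni_jel(x, 50, 1000), "baseline")
})

test_that("Uni-JEl recovers a sweep of generator elevations", {
  mesh <- make_rv_mesh(1, seed = 30)
  for (jel in c(0.2, 0.9, 2.0)) {
    sim <- make_study(mesh, 4, at_field = 20, ari_field = 250,
                      jel_field = jel, reference_annotation = 300,
                      duration_ms = 1000, seed = 31)
    f <- extract_features(sim$study)
    expect_equal(f$uni_jel_mv, rep(jel, 4), tolerance = 1e-6)
  }
})

test_that("AT equals the fiducial difference and matches brute-force search", {
  fs <- 1000
  sim <- tiny_study(10, seed = 32, noise_sd = 0.04)
  s <- sim$study
  w0 <- 201; w1 <- 401   # ref 300, woi [-100, 100]
  cfg <- feature_config()
  for (i in 1:10) {
    at <- compute_at(s$unipolar[i, ], s$ecg$V2, 300, c(-100, 100), fs, cfg)
    # exhaustive oracle over every sample of the window
    d <- epmap:::smoothed_derivative(s$unipolar[i, ], fs,
                                     cfg$derivative_smoothing_window_ms)
    u_fid <- w0 - 1 + which.min(d[w0:w1])
    v_fid <- w0 - 1 + which.min(s$ecg$V2[w0:w1])
    expect_identical(at, (u_fid - v_fid) * 1000 / fs)
  }
  # both fiducials coinciding gives 0 (downstroke centre = V2 minimum)
  tt <- seq_len(1000)
  u0 <- -plogis((tt - 300) / 2.5)
  v0 <- -exp(-(tt - 300)^2 / 50)
  expect_equal(compute_at(u0, v0, 300, c(-50, 50), fs), 0)
})

test_that("ARI matches the Wyatt construction and sweeps recover truth", {
  mesh <- make_rv_mesh(1, seed = 33)
  for (ari in c(180, 250, 320)) {
    sim <- make_study(mesh, 3, at_field = 10, ari_field = ari,
                      jel_field = 0.5, reference_annotation = 300,
                      duration_ms = 1000, seed = 34)
    f <- extract_features(sim$study)
    expect_lte(max(abs(f$ari_ms - ari)), 1 + 1e-9)
    expect_true(all(f$quality))
  }
  # search window exceeding the trace errors
  u <- make_unipolar_egm(ref_ms = 300, duration_ms = 1000)
  expect_error(compute_ari(u[1:500], 300, c(-100, 100), 1000), "exceeds")
})

test_that("Bazett correction: closed forms and monotonicity", {
  expect_equal(compute_aric(250, 1000), 250)
  expect_equal(compute_aric(250, 640), 312.5)
  expect_error(compute_aric(250, 0), "positive")
  rr <- seq(400, 1600, by = 100)
  expect_true(all(diff(compute_aric(250, rr)) < 0))
})

test_that("peak-to-peak voltage equals exhaustive max - min", {
  fs <- 1000
  tt <- seq_len(1000)
  x <- 2 * sin(2 * pi * tt / 100)
  expect_equal(compute_unipolar_voltage(x, 500, c(-100, 100), fs), 4,
               tolerance = 1e-3)
  expect_equal(compute_unipolar_voltage(rep(3, 1000), 500, c(-100, 100), fs), 0)
  set.seed(40)
  for (i in 1:20) {
    y <- rnorm(1000)
    seg <- y[401:601]
    expect_identical(compute_unipolar_voltage(y, 500, c(-100, 100), fs),
                     max(seg) - min(seg))
  }
})

test_that("quality rejection triggers with the correct reason codes", {
  fs <- 1000
  sim <- tiny_study(1, seed = 35)
  u <- sim$study$unipolar[1, ]
  ref <- 300; woi <- c(-100, 100)
  clean <- compute_ari(u, ref, woi, fs)
  expect_identical(clean$quality$reason, "ok")
  expect_true(clean$quality$accepted)

  # white noise only: rejected as noise
  set.seed(36)
  noisy <- rnorm(length(u), sd = 1)
  v <- compute_ari(noisy, ref, woi, fs)
  expect_identical(v$quality$reason, "noise")
  expect_false(v$quality$accepted)

  # injected second depolarization inside the woi: premature beat
  u2 <- u + epmap:::egm_bank_clean((seq_along(u) - 1), ref + 80, 250, 0,
                                   ref + 95, 2, 0)[1, ]
  v2 <- compute_ari(u2, ref, woi, fs)
  expect_identical(v2$quality$reason, "premature_beat")

  # T fiducial clamped at the search boundary: abnormal morphology
  flat_t <- u
  flat_t[(321 + 100):length(u)] <- flat_t[321 + 100]   # amputate the T wave
  v3 <- compute_ari(flat_t, ref, woi, fs)
  expect_identical(v3$quality$reason, "abnormal_t_morphology")
})

test_that("translation and amplitude-scaling invariances hold", {
  fs <- 1000
  sim <- tiny_study(4, seed = 37, noise_sd = 0.03)
  s <- sim$study
  cfg <- feature_config()
  for (i in 1:4) {
    u <- s$unipolar[i, ]; v2 <- s$ecg$V2
    at0 <- compute_at(u, v2, 300, c(-100, 100), fs, cfg)
    ari0 <- compute_ari(u, 300, c(-100, 100), fs, cfg)$ari_ms
    # shift by 40 samples
    sh <- function(x) c(numeric(40), x)
    expect_equal(compute_at(sh(u), sh(v2), 340, c(-100, 100), fs, cfg), at0)
    expect_equal(compute_ari(sh(u), 340, c(-100, 100), fs, cfg)$ari_ms, ari0)
    # scale by k > 0: AT/ARI unchanged, voltage scales
    expect_equal(compute_at(3 * u, v2, 300, c(-100, 100), fs, cfg), at0)
    expect_equal(compute_ari(3 * u, 300, c(-100, 100), fs, cfg)$ari_ms, ari0)
    expect_equal(compute_unipolar_voltage(3 * u, 300, c(-100, 100), fs),
                 3 * compute_unipolar_voltage(u, 300, c(-100, 100), fs))
  }
})

test_that("RR estimation and the fallback message", {
  v2 <- epmap:::make_v2_trace(1000, 2000, 2701)
  expect_equal(estimate_rr(v2, 1000), 1000)
  s <- tiny_study(2, seed = 38)$study   # single beat at ref 300
  expect_message(extract_features(s), "1000 ms")
})
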