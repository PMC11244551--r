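test_that("conditions evaluate correctly, including missing values", {
  v <- c(1, 2, 3, NA)
  expect_identical(epmap:::condition_satisfied(v, epm_condition("f", "le", 2)),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(epmap:::condition_satisfied(v, epm_condition("f", "within",
                                                                1.5, 3)),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_error(epm_condition("f", "within", 3, 1), "value2")
})

test_that("area_where: everywhere, nowhere, and an exact half split", {
  m <- strip_mesh(4)
  all_sat <- area_where(m, rep(1, nrow(m$vertices)),
                        epm_condition("f", "ge", 0))
  expect_equal(unname(all_sat), c(4, 100))
  none <- area_where(m, rep(1, nrow(m$vertices)), epm_condition("f", "gt", 2))
  expect_equal(unname(none), c(0, 0))
  # step field aligned with the triangle boundary at x = 2: exactly half
  fld <- as.numeric(m$vertices[, 1] <= 2)
  half <- area_where(m, fld, epm_condition("f", "ge", 0.5))
  expect_equal(unname(half), c(2, 50))
})

test_that("area_where is monotone in the threshold", {
  m <- make_rv_mesh(2, seed = 70)
  set.seed(71)
  fld <- rnorm(nrow(m$vertices))
  a <- vapply(seq(-2, 2, by = 0.5), function(thr)
    area_where(m, fld, epm_condition("f", "le", thr))[["area_mm2"]], 1)
  expect_true(all(diff(a) >= 0))
})

test_that("joint areas: tautology, disjoint regions, exhaustive oracle", {
  m <- make_rv_mesh(1, seed = 72)
  set.seed(73)
  fa <- rnorm(nrow(m$vertices)); fb <- rnorm(nrow(m$vertices))
  ca <- epm_condition("a", "ge", 0); taut <- epm_condition("b", "ge", -Inf)
  expect_equal(area_where_joint(m, fa, ca, fb, taut), area_where(m, fa, ca))
  # disjoint satisfied sets
  left <- as.numeric(m$vertices[, 1] < 0)
  expect_equal(unname(area_where_joint(m, left, epm_condition("a", "ge", 1),
                                       left, epm_condition("b", "le", 0))),
               c(0, 0))
  # oracle: per-triangle evaluation
  cb <- epm_condition("b", "le", 0.3)
  got <- area_where_joint(m, fa, ca, fb, cb)
  areas <- triangle_areas(m)
  want <- 0
  for (t in seq_len(nrow(m$triangles))) {
    vs <- m$triangles[t, ]
    if (all(fa[vs] >= 0) && all(fb[vs] <= 0.3)) want <- want + areas[t]
  }
  expect_equal(got[["area_mm2"]], want)
  # joint area cannot exceed either individual area
  expect_lte(got[["area_mm2"]], area_where(m, fa, ca)[["area_mm2"]])
  expect_lte(got[["area_mm2"]], area_where(m, fb, cb)[["area_mm2"]])
})

test_that("binary fields are 0/1 with missing preserved and idempotent", {
  fld <- c(0.2, 0.9, NA, 1.4)
  cond <- epm_condition("f", "ge", 0.85)
  b <- binary_field(fld, cond)
  expect_identical(b, c(0, 1, NA, 1))
  expect_identical(binary_field(b, epm_condition("f", "ge", 0.85)),
                   c(0, 1, NA, 1))
  expect_identical(binary_field(c(1, 1), epm_condition("f", "lt", 1)), c(0, 0))
  expect_identical(binary_field(c(1, 2), epm_condition("f", "ge", 1)), c(1, 1))
})

test_that("summary statistics match direct formulas", {
  s <- summarize_stats(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5); expect_equal(s$median, 2.5)
  expect_equal(s$range, 3)
  one <- summarize_stats(42)
  expect_identical(one$n, 1L)
  expect_true(is.na(one$sd))
  expect_equal(one$iqr, 0); expect_equal(one$range, 0)
  expect_identical(summarize_stats(numeric(0))$n, 0L)
  set.seed(74)
  for (rep in 1:5) {
    x <- rnorm(sample(5:60, 1))
    s <- summarize_stats(x)
    expect_equal(s$mean, sum(x) / length(x), tolerance = 1e-12)
    expect_equal(s$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                 tolerance = 1e-12)
    expect_equal(s$iqr, unname(quantile(x, 0.75) - quantile(x, 0.25)),
                 tolerance = 1e-12)
    expect_equal(s$range, max(x) - min(x), tolerance = 1e-12)
  }
})

test_that("RVAT is the activation-time spread", {
  expect_equal(rvat(c(5, 20, 42)), 37)
  expect_equal(rvat(rep(7, 10)), 0)
  expect_error(rvat(5), "at least 2")
  m <- make_rv_mesh(1, seed = 75)
  flds <- varying_fields(m)
  sim <- make_study(m, 40, at_field = flds$at, ari_field = 250,
                    jel_field = 0.5, reference_annotation = 300,
                    duration_ms = 1000, seed = 76)
  f <- extract_features(sim$study)
  expect_equal(rvat(f$at_ms), max(sim$truth$at_ms) - min(sim$truth$at_ms),
               tolerance = 1e-9)
})

test_that("voltage presets are nested", {
  p <- preset_conditions()
  m <- make_rv_mesh(1, seed = 77)
  set.seed(78)
  fld <- runif(nrow(m$vertices), 0, 10)
  a44 <- area_where(m, fld, p$uni_le_4p4)[["area_mm2"]]
  a53 <- area_where(m, fld, p$uni_le_5p3)[["area_mm2"]]
  expect_lte(a44, a53)
})

test_that("roi_median_condition implements the median-threshold recipe", {
  cond <- roi_median_condition(c(0.5, 0.85, 1.2), "delta_uni_jel_mv")
  expect_identical(cond$op, "ge")
  expect_equal(cond$value, 0.85)
  expect_error(roi_median_condition(numeric(0), "x"), "no delta")
})

test_that("report: row structure and byte-identical reruns", {
  sim <- tiny_study(18, seed = 79)
  s <- sim$study
  r1 <- build_report(list(pre = s), conditions = preset_conditions())
  expect_identical(nrow(r1), 5L)   # 5 features x 1 study x ALL
  roi <- define_roi(s$mesh, equator_picks(s$mesh))
  r2 <- build_report(list(pre = s), rois = list(rvot = roi),
                     conditions = preset_conditions())
  expect_identical(nrow(r2), 10L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  build_report(list(pre = s), rois = list(rvot = roi),
               conditions = preset_conditions(), path = f1)
  build_report(list(pre = s), rois = list(rvot = roi),
               conditions = preset_conditions(), path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(all(c("area_mm2_uni_le_4p4", "area_pct_uni_le_5p3") %in%
                    names(r2)))
})
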