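test_that("boresight cell of the simple field closes the calibration loop", {
  sys <- calibrated_system()
  pat <- gaussian_pattern()
  field <- simulate_field(sys, pat, cm2_to_m2(12.7),
                          distances_m = seq(100, 900, 100),
                          heights_m = c(0, 2, 10))
  # at d = 800 m, h = h_R the gain is peak and P ~ P_min
  p <- field$power_w[field$heights_m == 2, field$distances_m == 800]
  expect_equal(watts_to_dbm(p), -74, tolerance = 0.05)
  expect_equal(field$mode, "simple")
})

test_that("advanced mode suppresses the ground and converges to simple aloft", {
  sys <- calibrated_system()
  pat <- gaussian_pattern()
  d <- seq(10, 1000, 10)
  h <- seq(0, 300, 2)
  simple <- simulate_field(sys, pat, cm2_to_m2(12.7), NULL, d, h)
  adv <- simulate_field(sys, pat, cm2_to_m2(12.7), study_fence(), d, h)
  # ground cell at 500 m: at least 20 dB below simple (two-way)
  i <- which(h == 0); j <- which(d == 500)
  drop_db <- 10 * log10(simple$power_w[i, j] / adv$power_w[i, j])
  expect_gt(drop_db, 20)
  # far above the edge the fence has no effect; the fringe envelope
  # decays as 1/(pi v1), ~0.3 dB two-way at v1 = -10
  lam <- wavelength(sys)
  v1 <- outer(h, d, function(hh, dd) {
    edge_fresnel_v(study_fence(), dd, hh, lam)
  })
  open_sky <- v1 < -10
  rel_db <- abs(10 * log10(simple$power_w[open_sky] / adv$power_w[open_sky]))
  expect_lt(max(rel_db), 0.5)
  # ground-level detectable extent never grows under the fence
  pminw <- sys$min_detectable_power_w
  low <- h < sys$antenna_height_m
  expect_true(all(colSums(adv$power_w[low, , drop = FALSE] >= pminw) <=
                  colSums(simple$power_w[low, , drop = FALSE] >= pminw)))
})

test_that("isotropic boundary matches the circular-arc closed form", {
  sys <- calibrated_system()
  iso <- isotropic_pattern(31.6)
  sigma <- cm2_to_m2(12.7)
  r_max <- max_detection_range(sys, sigma)
  d <- seq(5, 1000, 5)
  h <- seq(0, 900, 1)
  field <- simulate_field(sys, iso, sigma, NULL, d, h)
  b <- extract_boundary(field, sys$min_detectable_power_w)
  expect_equal(b$max_range_m, r_max, tolerance = 5 / r_max)
  # h(d) = clip(h_R + sqrt(R^2 - d^2)) - clip(h_R - sqrt(...)) on the grid
  for (dd in c(100, 400, 700)) {
    s <- sqrt(r_max^2 - dd^2)
    want <- min(900, 2 + s) - max(0, 2 - s)
    expect_equal(detection_height_at(b, dd), want, tolerance = 2 / want)
  }
  # single ground-based interval per distance in simple mode
  n_iv <- vapply(b$intervals, nrow, integer(1))
  expect_true(all(n_iv <= 1))
  expect_true(all(vapply(b$intervals[n_iv == 1],
                         function(iv) iv[1, "low_m"] == 0, logical(1))))
  # detectable extent shrinks towards the maximum range
  hh <- detection_height_at(b, c(100, 400, 700, 790))
  expect_true(all(diff(hh) < 0))
})

test_that("boundary extraction handles empty and default-pattern cases", {
  sys <- calibrated_system()
  pat <- gaussian_pattern()
  sigma <- cm2_to_m2(12.7)
  field <- simulate_field(sys, pat, sigma,
                          distances_m = seq(5, 1000, 5))
  b <- extract_boundary(field, sys$min_detectable_power_w)
  # the bat model's maximum range, within grid + calibration rounding
  expect_equal(b$max_range_m, 800, tolerance = 0.01)
  # a threshold above everything leaves nothing detectable
  empty <- extract_boundary(field, max(field$power_w) * 2)
  expect_equal(empty$max_range_m, 0)
  expect_equal(detection_height_at(empty, 100), 0)
  # beyond max range the detection height is 0
  expect_equal(detection_height_at(b, 1500), 0)
})

test_that("summed interval extents drive detection height in advanced mode", {
  sys <- calibrated_system()
  pat <- gaussian_pattern()
  field <- simulate_field(sys, pat, cm2_to_m2(12.7), study_fence(),
                          distances_m = seq(10, 1000, 10),
                          heights_m = seq(0, 300, 1))
  b <- extract_boundary(field, sys$min_detectable_power_w)
  j <- which(b$distances_m == 400)
  iv <- b$intervals[[j]]
  expect_equal(detection_height_at(b, 400),
               sum(iv[, "high_m"] - iv[, "low_m"]))
  # the fence raises the lower boundary off the ground at long range
  expect_gt(iv[1, "low_m"], 0)
})

test_that("the boundary is stable under grid refinement", {
  sys <- calibrated_system()
  pat <- gaussian_pattern()
  sigma <- cm2_to_m2(12.7)
  coarse <- extract_boundary(
    simulate_field(sys, pat, sigma, NULL, seq(10, 1000, 10), seq(0, 300, 2)),
    sys$min_detectable_power_w)
  fine <- extract_boundary(
    simulate_field(sys, pat, sigma, NULL, seq(5, 1000, 5), seq(0, 300, 1)),
    sys$min_detectable_power_w)
  expect_lt(abs(coarse$max_range_m - fine$max_range_m), 10 + 1e-9)
  for (dd in c(200, 500, 750)) {
    expect_lt(abs(detection_height_at(coarse, dd) -
                  detection_height_at(fine, dd)), 4 + 1e-9)
  }
})

test_that("boundary and field exports are readable tables", {
  sys <- calibrated_system()
  pat <- gaussian_pattern()
  field <- simulate_field(sys, pat, cm2_to_m2(12.7),
                          distances_m = seq(100, 800, 100),
                          heights_m = seq(0, 100, 10))
  b <- extract_boundary(field, sys$min_detectable_power_w)
  bpath <- withr::local_tempfile(fileext = ".tsv")
  write_boundary(b, bpath)
  btab <- read.table(bpath, header = TRUE)
  expect_named(btab, c("distance_m", "interval_low_m", "interval_high_m"))
  expect_true(all(btab$interval_high_m >= btab$interval_low_m))
  fpath <- withr::local_tempfile(fileext = ".tsv")
  write_field(field, fpath)
  ftab <- read.table(fpath, header = TRUE)
  expect_equal(nrow(ftab), length(field$heights_m))
  expect_equal(ncol(ftab), 1 + length(field$distances_m))
})
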