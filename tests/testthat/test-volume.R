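# Brute-force per-pixel reimplementation of the volume sum, used as the
# oracle for integrate_volume on small images.
brute_force_volume <- function(mask, boundary) {
  a_px <- mask$meters_per_pixel^2
  v <- 0
  n <- 0
  for (i in seq_len(nrow(mask$visible))) {
    for (j in seq_len(ncol(mask$visible))) {
      if (!mask$visible[i, j]) next
      n <- n + 1
      d <- sqrt((i - mask$origin[1])^2 + (j - mask$origin[2])^2) *
        mask$meters_per_pixel
      v <- v + a_px * detection_height_at(boundary, d)
    }
  }
  list(v = v, n = n)
}

simple_boundary <- function() {
  sys <- calibrated_system()
  extract_boundary(
    simulate_field(sys, gaussian_pattern(), cm2_to_m2(12.7), NULL,
                   seq(10, 1000, 10), seq(0, 300, 2)),
    sys$min_detectable_power_w)
}

test_that("volume integration equals the brute-force pixel loop", {
  b <- simple_boundary()
  img <- render_scene(demo_scene())
  # crop to a small image for the quadratic-cost oracle
  small <- ppi_image(img$levels[33:96, 33:96], img$meters_per_pixel,
                     c(32, 32))
  sec <- sector_spec(15, 175, 180)
  for (thr in c(0, 8, 24)) {
    m <- visibility_mask(small, sec, thr)
    got <- integrate_volume(m, b)
    want <- brute_force_volume(m, b)
    expect_equal(got$total_volume_m3, want$v, tolerance = 1e-12)
    expect_equal(got$visible_pixel_count, want$n)
  }
})

test_that("degenerate volumes behave: empty mask and single pixel", {
  b <- simple_boundary()
  lv <- matrix(31L, 16, 16)
  img_full <- ppi_image(lv, 3.027, c(8, 8))
  sec <- sector_spec(0, 0, 500)
  m_empty <- visibility_mask(img_full, sec, 0)  # everything above threshold
  expect_equal(integrate_volume(m_empty, b)$total_volume_m3, 0)
  expect_equal(integrate_volume(m_empty, b)$visible_pixel_count, 0)
  # one visible pixel contributes A_px * h(d)
  lv[3, 8] <- 0L
  img_one <- ppi_image(lv, 3.027, c(8, 8))
  m_one <- visibility_mask(img_one, sec, 0)
  expect_equal(m_one$visible_count, 1)
  d <- 5 * 3.027
  expect_equal(integrate_volume(m_one, b)$total_volume_m3,
               3.027^2 * detection_height_at(b, d))
})

test_that("a clutter-free annulus sums to count x area x height", {
  # constant-height boundary: flat detection up to 1 km
  flat <- structure(
    list(distances_m = seq(10, 1000, 10),
         intervals = rep(list(cbind(low_m = 0, high_m = 100)), 100),
         max_range_m = 1000, mode = "simple"),
    class = "detection_boundary")
  img <- zero_img <- ppi_image(matrix(0L, 64, 64), 3.027, c(32, 32))
  sec <- sector_spec(0, 90, 80)
  m <- visibility_mask(img, sec, 0)
  expect_equal(integrate_volume(m, flat)$total_volume_m3,
               m$visible_count * 3.027^2 * 100)
})

test_that("sector extrapolation and the acoustic comparison are linear", {
  expect_equal(sector_extrapolate(0.0105e9, 105, 360), 0.036e9)
  expect_equal(sector_extrapolate(1000, 90, 90), 1000)
  expect_equal(sector_extrapolate(1000, 45, 90), 2000)
  expect_equal(acoustic_hemisphere_volume(40), 2 / 3 * pi * 40^3)
  expect_equal(acoustic_hemisphere_volume(40), 1.3404e5, tolerance = 1e-4)
  expect_equal(acoustic_hemisphere_volume(1), 2 * pi / 3)
  expect_equal(acoustic_hemisphere_volume(2), 8 * acoustic_hemisphere_volume(1))

  r <- volume_ratio_vs_acoustic(0.0105e9, 105, 40)
  expect_equal(r$ratio, 268.6, tolerance = 1e-3)
  expect_equal(r$ratio_rounded, 270)
  expect_equal(volume_ratio_vs_acoustic(0.0105e9 / 2, 105, 40)$ratio,
               r$ratio / 2)
  expect_equal(volume_ratio_vs_acoustic(0.0105e9, 105, 80)$ratio,
               r$ratio / 8, tolerance = 1e-12)
})

test_that("the fence sweep rewards suppressed clutter on paired scenes", {
  sys <- calibrated_system()
  pat <- gaussian_pattern()
  # heavy ground clutter ring that the fence pushes below threshold
  spec <- scene_spec(
    size_px = 96, seed = 11,
    clutter_blobs = list(
      list(center = c(30, 60), radius_px = 14, base_level = 12,
           fluctuation_amplitude = 1),
      list(center = c(60, 30), radius_px = 12, base_level = 14,
           fluctuation_amplitude = 1)))
  img <- render_scene(spec)
  sec <- sector_spec(0, 0, 150)
  sweep <- optimization_sweep(sys, pat, cm2_to_m2(12.7), img, sec,
                              study_fence(), h_cfr_values_m = 0.2,
                              thresholds = c(0, 8),
                              distances_m = seq(10, 1000, 20),
                              heights_m = seq(0, 300, 4))
  expect_named(sweep, c("h_cfr_m", "threshold", "volume_no_csf_m3",
                        "volume_csf_m3", "ratio"))
  # at threshold 8 the unsuppressed clutter (levels ~11-15) blocks pixels
  # that the fence-attenuated image frees: ratio > 1
  row8 <- sweep[sweep$threshold == 8, ]
  expect_gt(row8$ratio, 1)
  # volumes grow with the threshold in both columns
  expect_true(all(diff(sweep$volume_no_csf_m3) >= 0))
  expect_true(all(diff(sweep$volume_csf_m3) >= 0))
})

test_that("sweep output files carry the table and a JSON summary", {
  sweep <- data.frame(h_cfr_m = c(0.2, 0.2), threshold = c(0, 8),
                      volume_no_csf_m3 = c(1e6, 2e6),
                      volume_csf_m3 = c(1.5e6, 3e6), ratio = c(1.5, 1.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sweep(sweep, path)
  tab <- read.table(path, header = TRUE)
  expect_equal(nrow(tab), 2)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$best_threshold, 8)
  expect_equal(js$best_volume_csf_m3, 3e6)
})
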