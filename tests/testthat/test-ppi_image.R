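zero_image <- function(n = 64, mpp = 3.027) {
  ppi_image(matrix(0L, n, n), mpp, origin = c(n / 2, n / 2))
}

test_that("image construction validates levels and geometry", {
  img <- zero_image()
  expect_equal(pixel_area(img), 3.027^2)
  expect_equal(pixel_area(img), 9.16, tolerance = 1e-3)
  expect_error(ppi_image(matrix(32, 4, 4), 3, c(2, 2)), "0, 31")
  expect_error(ppi_image(matrix(-1, 4, 4), 3, c(2, 2)), "0, 31")
  expect_error(ppi_image(matrix(0, 4, 4), 3, c(9, 2)), "origin")
})

test_that("visibility masks combine sector, range and threshold", {
  img <- zero_image(64)
  sec <- sector_spec(0, 90, 1000)
  m <- visibility_mask(img, sec, 0)
  # all-zero image at threshold 0: every in-sector in-range pixel visible
  geo_dist <- m$distance_m
  expect_gt(m$visible_count, 0)
  expect_false(m$visible[img$origin[1], img$origin[2]])  # origin never
  expect_true(all(geo_dist[m$visible] <= 1000))
  expect_true(all(geo_dist[m$visible] > 0))

  # boundary semantics: level 12 invisible at threshold 11, visible at 12
  lv <- matrix(0L, 64, 64)
  lv[10, 40] <- 12L
  img2 <- ppi_image(lv, 3.027, c(32, 32))
  expect_false(visibility_mask(img2, sec, 11)$visible[10, 40])
  expect_true(visibility_mask(img2, sec, 12)$visible[10, 40])

  expect_error(visibility_mask(img, sec, 40), "0, 31")
})

test_that("visible count is monotone in threshold and additive over sectors", {
  img <- render_scene(demo_scene())
  sec <- sector_spec(20, 200, 180)
  counts <- vapply(0:31, function(thr) {
    visibility_mask(img, sec, thr)$visible_count
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # complement sector partitions the full circle
  comp <- sector_spec(200, 20, 180)
  full <- sector_spec(0, 0, 180)  # coincident bearings = full circle
  expect_equal(sector_angle(full), 360)
  for (thr in c(0, 8, 20)) {
    expect_equal(visibility_mask(img, sec, thr)$visible_count +
                   visibility_mask(img, comp, thr)$visible_count,
                 visibility_mask(img, full, thr)$visible_count)
  }
})

test_that("sector angles follow clockwise-from-start convention", {
  expect_equal(sector_angle(sector_spec(25, 120, 1000)), 95)
  expect_equal(sector_angle(sector_spec(300, 30, 1000)), 90)
})

test_that("echo matrix mean analyzes the 3x3 block at the brightest pixel", {
  lv <- matrix(0L, 32, 32)
  # uniform 3x3 block of 31: the analysis mean is 31
  lv[15:17, 20:22] <- 31L
  img <- ppi_image(lv, 3.027, c(16, 16))
  res <- echo_matrix_mean(img, c(16, 21))
  expect_equal(res$mean_level, 31)
  expect_equal(res$peak, c(16, 21))
  # a weaker uniform block reads below the visibility threshold
  lv2 <- matrix(0L, 32, 32)
  lv2[15:17, 20:22] <- 18L
  res2 <- echo_matrix_mean(ppi_image(lv2, 3.027, c(16, 16)), c(16, 21))
  expect_equal(res2$mean_level, 18)
  # single bright pixel: mean 31/9 over the 3x3 block
  lv3 <- matrix(0L, 32, 32)
  lv3[16, 21] <- 31L
  res3 <- echo_matrix_mean(ppi_image(lv3, 3.027, c(16, 16)), c(16, 21))
  expect_equal(res3$mean_level, 31 / 9)
  expect_equal(res3$peak, c(16, 21))
  # the search window locates a peak off the declared sample point
  res4 <- echo_matrix_mean(ppi_image(lv3, 3.027, c(16, 16)), c(18, 23))
  expect_equal(res4$peak, c(16, 21))
  expect_error(echo_matrix_mean(img, c(40, 2)), "outside")
})

test_that("the multi-frame rule requires a strict majority", {
  mk_stack <- function(levels_per_frame) {
    frames <- lapply(levels_per_frame, function(l) {
      lv <- matrix(0L, 32, 32)
      lv[15:17, 20:22] <- as.integer(l)
      ppi_image(lv, 3.027, c(16, 16))
    })
    echo_stack(frames, c(16, 21))
  }
  six <- mk_stack(c(rep(31, 6), rep(18, 5)))
  expect_true(stack_visibility(six)$visible)
  expect_equal(stack_visibility(six)$v, 6)
  five <- mk_stack(c(rep(31, 5), rep(18, 6)))
  expect_false(stack_visibility(five)$visible)
  none <- mk_stack(rep(10, 11))
  expect_equal(stack_visibility(none)$v, 0)
  expect_false(stack_visibility(none)$visible)
  # frame 25 exactly at the mean threshold counts as passing
  at25 <- mk_stack(c(rep(25, 6), rep(18, 5)))
  expect_true(stack_visibility(at25)$visible)
  expect_error(echo_stack(list(zero_image(), zero_image()), c(3, 3)), "odd")
})

test_that("max visible distance reproduces the field campaign decisions", {
  bat <- c("350" = 11, "500" = 10, "650" = 9, "800" = 6, "950" = 0)
  expect_equal(max_visible_distance(bat), 800)
  dead_bat <- c("350" = 10, "500" = 4, "650" = 11, "800" = 0, "950" = 0)
  expect_equal(max_visible_distance(dead_bat), 650)
  empty_bottle <- c("350" = 10, "500" = 0, "650" = 0, "800" = 0, "950" = 0)
  expect_equal(max_visible_distance(empty_bottle), 350)
  # no distance visible is NA, not 0
  expect_true(is.na(max_visible_distance(c("350" = 5, "500" = 0))))
  expect_error(max_visible_distance(c("350" = 12)), "total_frames")
})

test_that("masking an already-masked image is a no-op", {
  img <- render_scene(demo_scene())
  sec <- sector_spec(10, 170, 150)
  m1 <- visibility_mask(img, sec, 8)
  # paint masked-out pixels opaque and re-mask: same visibility
  lv <- img$levels
  lv[!m1$visible] <- 31L
  masked <- ppi_image(lv, img$meters_per_pixel, img$origin)
  m2 <- visibility_mask(masked, sec, 8)
  expect_equal(m2$visible, m1$visible)
})

test_that("text and PNG image round-trips preserve levels and geometry", {
  img <- render_scene(demo_scene())
  tpath <- withr::local_tempfile(fileext = ".txt")
  write_ppi_text(img, tpath)
  back <- read_ppi_text(tpath)
  expect_equal(back$levels, img$levels, ignore_attr = TRUE)
  expect_equal(back$meters_per_pixel, img$meters_per_pixel)
  expect_equal(back$origin, img$origin)
  ppath <- withr::local_tempfile(fileext = ".png")
  write_ppi_png(img, ppath)
  back_png <- read_ppi_png(ppath, img$meters_per_pixel, img$origin)
  expect_equal(back_png$levels, img$levels, ignore_attr = TRUE)
})
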