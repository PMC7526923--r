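# Seeded synthetic PPI scenes: level-quantized images with fluctuating
# clutter blobs and point echoes, frame stacks exercising the multi-frame
# visibility rule, and paired with/without-fence scenes in which clutter
# is attenuated by the fence's two-way knife-edge suppression. Everything
# is reproducible from the scene seed; no field data is required to test
# the pipeline end to end. The blobs and discs emulate the *structure* of
# real cluttered scenes (fluctuating intensities spanning several levels),
# not the statistics of real land clutter.

#' Specify a synthetic PPI scene
#'
#' @param size_px image edge length in pixels (square image).
#' @param meters_per_pixel ground resolution (default 3.027 m/px).
#' @param origin radar pixel `c(row, col)`; defaults to the image center.
#' @param clutter_blobs list of blobs, each a list with `center`
#'   (`c(row, col)`), `radius_px`, `base_level` (0-31) and
#'   `fluctuation_amplitude` (integer levels).
#' @param point_echoes list of echoes, each a list with `bearing_deg`,
#'   `range_m`, `mean_level` (0-31) and `fluctuation_amplitude`.
#' @param seed integer RNG seed; identical seeds give identical scenes.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(size_px = 256, meters_per_pixel = 3.027,
                       origin = NULL, clutter_blobs = list(),
                       point_echoes = list(), seed = 1L) {
  stopifnot(size_px >= 8)
  if (is.null(origin)) origin <- c(ceiling(size_px / 2), ceiling(size_px / 2))
  structure(
    list(size_px = as.integer(size_px), meters_per_pixel = meters_per_pixel,
         origin = as.numeric(origin), clutter_blobs = clutter_blobs,
         point_echoes = point_echoes, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px, %d blobs, %d echoes, seed %d\n",
              x$size_px, x$size_px, length(x$clutter_blobs),
              length(x$point_echoes), x$seed))
  invisible(x)
}

# pmin/pmax take attributes from their first argument; assign in place
# so matrix dims survive
clamp_level <- function(x) {
  x[] <- pmin(31, pmax(0, round(x)))
  x
}

# (row, col) of the pixel whose center is nearest to the polar position.
echo_pixel <- function(spec, bearing_deg, range_m) {
  b <- bearing_deg * pi / 180
  px <- range_m / spec$meters_per_pixel
  c(round(spec$origin[1] - px * cos(b)), round(spec$origin[2] + px * sin(b)))
}

#' Render a synthetic PPI scene
#'
#' Clutter blobs are filled discs at their base level; point echoes are
#' 3x3 blocks centered at their polar position at their mean level. Every
#' painted pixel then receives seeded integer noise uniform in
#' +/- its fluctuation amplitude, and levels are clamped to \[0, 31\].
#' The returned image carries a `clutter_mask` attribute (logical matrix,
#' TRUE on blob pixels) used by the with/without-fence pairing.
#'
#' @param spec a [scene_spec()].
#' @param frame_index offset added to the seed so that consecutive frames
#'   of one scene fluctuate independently but reproducibly.
#' @return a [ppi_image()].
#' @export
render_scene <- function(spec, frame_index = 0L) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$size_px
  lv <- matrix(0, n, n)
  clutter <- matrix(FALSE, n, n)
  withr::with_seed(spec$seed + frame_index, {
    for (b in spec$clutter_blobs) {
      dr <- outer(seq_len(n) - b$center[1], rep(1, n))
      dc <- outer(rep(1, n), seq_len(n) - b$center[2])
      disc <- dr^2 + dc^2 <= b$radius_px^2
      amp <- b$fluctuation_amplitude
      noise <- if (amp > 0) sample(-amp:amp, sum(disc), replace = TRUE) else 0
      lv[disc] <- pmax(lv[disc], b$base_level + noise)
      clutter <- clutter | disc
    }
    for (e in spec$point_echoes) {
      px <- echo_pixel(spec, e$bearing_deg, e$range_m)
      if (px[1] < 2 || px[1] > n - 1 || px[2] < 2 || px[2] > n - 1) {
        stop("point echo outside image (needs a 1-pixel margin)",
             call. = FALSE)
      }
      amp <- e$fluctuation_amplitude
      block <- e$mean_level +
        if (amp > 0) sample(-amp:amp, 9, replace = TRUE) else 0
      rows <- (px[1] - 1):(px[1] + 1)
      cols <- (px[2] - 1):(px[2] + 1)
      lv[rows, cols] <- pmax(lv[rows, cols], matrix(block, 3, 3))
    }
  })
  img <- ppi_image(clamp_level(lv), spec$meters_per_pixel, spec$origin)
  attr(img, "clutter_mask") <- clutter
  img
}

#' Render a stack of frames with a planted pass pattern
#'
#' Frame i shows the scene's (single) point echo at a mean level at or
#' above the visibility threshold iff `pass_pattern[i]`; the exemplar
#' levels are 31 for a passing and 18 for a failing frame. Clutter blobs
#' fluctuate frame to frame under the scene seed.
#'
#' @param spec a [scene_spec()] with exactly one point echo (its position
#'   defines the sample point).
#' @param frames number of frames (default 11).
#' @param pass_pattern logical vector of length `frames`.
#' @param pass_level,fail_level echo mean levels for passing / failing
#'   frames (defaults 31 and 18).
#' @return an [echo_stack()] whose sample point is the echo position.
#' @export
render_stack <- function(spec, frames = 11, pass_pattern,
                         pass_level = 31, fail_level = 18) {
  stopifnot(inherits(spec, "scene_spec"), length(spec$point_echoes) == 1,
            length(pass_pattern) == frames)
  e <- spec$point_echoes[[1]]
  imgs <- lapply(seq_len(frames), function(i) {
    s <- spec
    s$point_echoes[[1]]$mean_level <- if (pass_pattern[i]) pass_level
                                      else fail_level
    render_scene(s, frame_index = i)
  })
  echo_stack(imgs, echo_pixel(spec, e$bearing_deg, e$range_m))
}

# Internal: derive the with-fence image from a without-fence image by
# attenuating clutter pixels by the fence's two-way suppression at their
# distance (ground level), quantized at level_step_db per level.
render_csf_pair_image <- function(image, geom, wavelength_m, clutter_mask,
                                  level_step_db = 3) {
  stopifnot(inherits(image, "ppi_image"))
  if (is.null(clutter_mask)) {
    stop("image carries no clutter mask; pass clutter_mask explicitly",
         call. = FALSE)
  }
  geo <- pixel_geometry(image)
  lv <- image$levels
  idx <- which(clutter_mask & geo$distance_m > geom$fence_radius_m)
  if (length(idx) > 0) {
    v1 <- edge_fresnel_v(geom, geo$distance_m[idx], 0, wavelength_m)
    two_way_db <- -20 * log10(knife_edge_intensity(v1))
    lv[idx] <- pmax(0, lv[idx] - round(two_way_db / level_step_db))
  }
  with_img <- ppi_image(lv, image$meters_per_pixel, image$origin)
  attr(with_img, "clutter_mask") <- clutter_mask
  with_img
}

#' Render a paired with/without-fence scene
#'
#' The "without" member is the plain rendered scene; the "with" member is
#' the same scene with every clutter pixel's level reduced by
#' round(two-way suppression / `level_step_db`), floored at level 0,
#' where the two-way suppression is the squared knife-edge factor of the
#' fence at the pixel's ground-level position. Point echoes (airborne
#' targets) are untouched. The 3 dB-per-level step is a fixture
#' convention (32 levels spanning ~96 dB of displayed dynamic range), not
#' a property of any real display.
#'
#' @param spec a [scene_spec()].
#' @param geom a [csf_geometry()].
#' @param system a [radar_system()] (supplies the wavelength).
#' @param level_step_db dB per intensity level (default 3).
#' @return list with components `without` and `with`, both
#'   [ppi_image()]s.
#' @export
render_csf_pair <- function(spec, geom, system, level_step_db = 3) {
  stopifnot(inherits(spec, "scene_spec"), inherits(geom, "csf_geometry"),
            inherits(system, "radar_system"))
  without <- render_scene(spec)
  with_img <- render_csf_pair_image(without, geom, wavelength(system),
                                    attr(without, "clutter_mask"),
                                    level_step_db)
  list(without = without, with = with_img)
}
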