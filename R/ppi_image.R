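# Quantized PPI (plan position indicator) radar image handling. The
# radar display quantizes echo strength into 32 intensity levels (0-31);
# the image is a north-up pixel grid with the radar at a fixed origin
# pixel. Visibility analysis: clutter-threshold masks over an angular
# sector (the horizontal step of the volume model) and the multi-frame
# echo-visibility procedure used in the calibration experiments.

#' Construct a quantized PPI image
#'
#' @param levels integer matrix of intensity levels, all in \[0, 31\].
#'   Rows run north to south (row 1 at top), columns west to east.
#' @param meters_per_pixel ground size of one pixel in meters (default
#'   3.027, the display resolution at a 1.5 km range setting).
#' @param origin radar position as `c(row, col)`, 1-based; must lie
#'   inside the image.
#' @return an object of class `ppi_image`.
#' @export
ppi_image <- function(levels, meters_per_pixel = 3.027, origin) {
  levels <- as.matrix(levels)
  if (any(levels != round(levels)) || any(levels < 0) || any(levels > 31)) {
    stop("levels must be integers in [0, 31]", call. = FALSE)
  }
  stopifnot(meters_per_pixel > 0, length(origin) == 2)
  if (origin[1] < 1 || origin[1] > nrow(levels) ||
      origin[2] < 1 || origin[2] > ncol(levels)) {
    stop("origin must lie inside the image", call. = FALSE)
  }
  structure(
    list(levels = levels, meters_per_pixel = meters_per_pixel,
         origin = as.numeric(origin)),
    class = "ppi_image"
  )
}

#' @export
print.ppi_image <- function(x, ...) {
  cat(sprintf(
    "<ppi_image> %d x %d px, %.3f m/px (A_px = %.2f m^2), origin (%g, %g)\n",
    nrow(x$levels), ncol(x$levels), x$meters_per_pixel, pixel_area(x),
    x$origin[1], x$origin[2]))
  invisible(x)
}

#' Ground area represented by one pixel
#'
#' A_px = (meters per pixel)^2; 9.16 m^2 at the default 3.027 m/px.
#'
#' @param image a [ppi_image()] (or a bare meters-per-pixel number).
#' @return pixel area in m^2.
#' @export
pixel_area <- function(image) {
  mpp <- if (inherits(image, "ppi_image")) image$meters_per_pixel else image
  mpp^2
}

# Center-to-center distances (m) and bearings (deg clockwise from north)
# of every pixel relative to the radar origin.
pixel_geometry <- function(image) {
  stopifnot(inherits(image, "ppi_image"))
  nr <- nrow(image$levels); nc <- ncol(image$levels)
  east <- outer(rep(1, nr), seq_len(nc) - image$origin[2])
  north <- outer(image$origin[1] - seq_len(nr), rep(1, nc))
  dist <- sqrt(east^2 + north^2) * image$meters_per_pixel
  bearing <- (atan2(east, north) * 180 / pi) %% 360
  list(distance_m = dist, bearing_deg = bearing)
}

#' Angular image sector
#'
#' A sector traversed clockwise from `start_bearing_deg` to
#' `end_bearing_deg` (degrees clockwise from north), limited to
#' `max_range_m` from the radar.
#'
#' @param start_bearing_deg start bearing in \[0, 360).
#' @param end_bearing_deg end bearing in \[0, 360).
#' @param max_range_m maximum range in meters (> 0).
#' @return an object of class `sector_spec`.
#' @export
sector_spec <- function(start_bearing_deg, end_bearing_deg, max_range_m) {
  stopifnot(start_bearing_deg >= 0, start_bearing_deg < 360,
            end_bearing_deg >= 0, end_bearing_deg < 360, max_range_m > 0)
  structure(
    list(start_bearing_deg = start_bearing_deg,
         end_bearing_deg = end_bearing_deg,
         max_range_m = max_range_m),
    class = "sector_spec"
  )
}

#' Angular width of a sector
#'
#' @param sector a [sector_spec()].
#' @return width in degrees in (0, 360\]; coincident start and end mean a
#'   full circle.
#' @export
sector_angle <- function(sector) {
  stopifnot(inherits(sector, "sector_spec"))
  a <- (sector$end_bearing_deg - sector$start_bearing_deg) %% 360
  if (a == 0) 360 else a
}

in_sector <- function(bearing_deg, sector) {
  width <- sector_angle(sector)
  ((bearing_deg - sector$start_bearing_deg) %% 360) <= width
}

#' Clutter-threshold visibility mask
#'
#' A pixel is visible iff it lies inside the sector, its center distance
#' from the radar is positive and at most the sector's maximum range, and
#' its intensity level is at or below the clutter threshold (clutter at
#' or below the threshold is tolerated; stronger clutter masks the
#' pixel). The radar-origin pixel is never visible.
#'
#' @param image a [ppi_image()].
#' @param sector a [sector_spec()].
#' @param clutter_threshold intensity level in \[0, 31\].
#' @return an object of class `visibility_mask`: logical matrix `visible`
#'   aligned to the image, `visible_count`, and the generating geometry.
#' @export
visibility_mask <- function(image, sector, clutter_threshold) {
  stopifnot(inherits(image, "ppi_image"), inherits(sector, "sector_spec"))
  if (clutter_threshold < 0 || clutter_threshold > 31) {
    stop("clutter_threshold must be in [0, 31]", call. = FALSE)
  }
  geo <- pixel_geometry(image)
  vis <- in_sector(geo$bearing_deg, sector) &
    geo$distance_m > 0 &
    geo$distance_m <= sector$max_range_m &
    image$levels <= clutter_threshold
  structure(
    list(visible = vis, visible_count = sum(vis),
         meters_per_pixel = image$meters_per_pixel,
         origin = image$origin, sector = sector,
         clutter_threshold = clutter_threshold,
         distance_m = geo$distance_m),
    class = "visibility_mask"
  )
}

#' @export
print.visibility_mask <- function(x, ...) {
  cat(sprintf("<visibility_mask> %d visible pixels (threshold %d, sector %g deg)\n",
              x$visible_count, x$clutter_threshold, sector_angle(x$sector)))
  invisible(x)
}

#' Mean intensity of the 3x3 analysis matrix around the brightest pixel
#'
#' Finds the brightest pixel within a square search window centered on
#' the declared sample point, then averages the 3x3 block centered on
#' that peak; block cells outside the image are excluded from the mean.
#' Ties between equally bright pixels go to the one with the brighter
#' 3x3 neighborhood (so a uniform bright block is analyzed at its
#' center, where the matrix mean equals the block level), and remaining
#' ties row-major first.
#'
#' @param image a [ppi_image()].
#' @param sample_point `c(row, col)` of the declared sample position.
#' @param search_window odd window edge length in pixels (default 11).
#' @return list with `mean_level` and `peak` (`c(row, col)`).
#' @export
echo_matrix_mean <- function(image, sample_point, search_window = 11) {
  stopifnot(inherits(image, "ppi_image"), length(sample_point) == 2,
            search_window >= 1, search_window %% 2 == 1)
  nr <- nrow(image$levels); nc <- ncol(image$levels)
  if (sample_point[1] < 1 || sample_point[1] > nr ||
      sample_point[2] < 1 || sample_point[2] > nc) {
    stop("sample_point outside image", call. = FALSE)
  }
  half <- (search_window - 1) / 2
  rows <- max(1, sample_point[1] - half):min(nr, sample_point[1] + half)
  cols <- max(1, sample_point[2] - half):min(nc, sample_point[2] + half)
  win <- image$levels[rows, cols, drop = FALSE]
  block_mean <- function(r, c) {
    mean(image$levels[max(1, r - 1):min(nr, r + 1),
                      max(1, c - 1):min(nc, c + 1)])
  }
  # candidates tied at the window maximum, in row-major order
  tied <- which(t(win) == max(win)) - 1
  cand <- cbind(rows[tied %/% ncol(win) + 1], cols[tied %% ncol(win) + 1])
  means <- mapply(block_mean, cand[, 1], cand[, 2])
  best <- which.max(means)  # first (row-major) of the tied best
  peak <- cand[best, ]
  list(mean_level = means[best], peak = peak)
}

#' Stack of consecutive PPI frames at one sample point
#'
#' @param frames list of [ppi_image()]s with identical geometry; an odd
#'   count (default experimental design: 11).
#' @param sample_point `c(row, col)` of the sample position, shared by
#'   all frames.
#' @return an object of class `echo_stack`.
#' @export
echo_stack <- function(frames, sample_point) {
  stopifnot(is.list(frames), length(frames) >= 1)
  if (length(frames) %% 2 == 0) {
    stop("frame count must be odd so the majority rule cannot tie",
         call. = FALSE)
  }
  ref <- frames[[1]]
  for (f in frames) {
    stopifnot(inherits(f, "ppi_image"))
    if (!identical(dim(f$levels), dim(ref$levels)) ||
        f$meters_per_pixel != ref$meters_per_pixel ||
        !identical(f$origin, ref$origin)) {
      stop("all frames must share geometry", call. = FALSE)
    }
  }
  structure(list(frames = frames, sample_point = as.numeric(sample_point)),
            class = "echo_stack")
}

#' Multi-frame echo visibility decision
#'
#' For each frame, the 3x3 matrix mean around the brightest pixel near
#' the sample point is compared against `mean_threshold` (level 25 by
#' default); frames at or above it increment the visibility counter v.
#' The sample point is "visible" when v strictly exceeds
#' `count_threshold` (default 5, i.e. more than half of 11 frames).
#'
#' @param stack an [echo_stack()].
#' @param mean_threshold intensity level the 3x3 mean must reach
#'   (default 25).
#' @param count_threshold frame count that v must strictly exceed
#'   (default 5).
#' @param search_window search window passed to [echo_matrix_mean()].
#' @return list with `visible` (logical), `v` (integer counter) and
#'   `per_frame` (logical vector of per-frame decisions).
#' @export
stack_visibility <- function(stack, mean_threshold = 25, count_threshold = 5,
                             search_window = 11) {
  stopifnot(inherits(stack, "echo_stack"))
  per <- vapply(stack$frames, function(f) {
    echo_matrix_mean(f, stack$sample_point, search_window)$mean_level >=
      mean_threshold
  }, logical(1))
  v <- sum(per)
  list(visible = v > count_threshold, v = v, per_frame = per)
}

#' Maximum visible distance from per-distance pass counts
#'
#' Applies the stack visibility rule (count strictly greater than
#' `total_frames * count_threshold / 11`, i.e. > 5 of 11 by default) to a
#' table of per-distance pass counts and returns the largest distance
#' that is visible.
#'
#' @param counts named numeric vector: names are distances in meters,
#'   values the number of passing frames at that distance.
#' @param total_frames frames per stack (default 11).
#' @param count_threshold threshold of the 11-frame rule (default 5).
#' @return largest visible distance in meters, or `NA_real_` when no
#'   distance is visible (distinct from a 0 m result).
#' @examples
#' max_visible_distance(c("350" = 11, "500" = 10, "650" = 9,
#'                        "800" = 6, "950" = 0))  # 800
#' @export
max_visible_distance <- function(counts, total_frames = 11,
                                 count_threshold = 5) {
  stopifnot(length(counts) > 0, !is.null(names(counts)))
  if (any(counts < 0 | counts > total_frames)) {
    stop("counts must lie in [0, total_frames]", call. = FALSE)
  }
  d <- as.numeric(names(counts))
  cut <- total_frames * count_threshold / 11
  ok <- counts > cut
  if (!any(ok)) return(NA_real_)
  max(d[ok])
}

#' Read a PPI image from a portable text matrix
#'
#' Whitespace-separated integer levels, one image row per line. Geometry
#' is supplied by arguments or by a YAML sidecar written by
#' [write_ppi_text()].
#'
#' @param path file path.
#' @param meters_per_pixel,origin geometry; when `NULL`, read from
#'   `<path>.yml`.
#' @return a [ppi_image()].
#' @export
read_ppi_text <- function(path, meters_per_pixel = NULL, origin = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (is.null(meters_per_pixel) || is.null(origin)) {
    side <- yaml::read_yaml(paste0(path, ".yml"))
    if (is.null(meters_per_pixel)) meters_per_pixel <- side$meters_per_pixel
    if (is.null(origin)) origin <- c(side$origin_row, side$origin_col)
  }
  ppi_image(m, meters_per_pixel, origin)
}

#' Write a PPI image as a portable text matrix plus YAML geometry sidecar
#'
#' @param image a [ppi_image()].
#' @param path file path; geometry goes to `<path>.yml`.
#' @return `path`, invisibly.
#' @export
write_ppi_text <- function(image, path) {
  stopifnot(inherits(image, "ppi_image"))
  utils::write.table(image$levels, path, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  yaml::write_yaml(
    list(meters_per_pixel = image$meters_per_pixel,
         origin_row = image$origin[1], origin_col = image$origin[2]),
    paste0(path, ".yml"))
  invisible(path)
}

#' Read a PPI image from an 8-bit grayscale PNG
#'
#' Levels are recovered as floor(gray / 8) from the 0-255 gray scale.
#'
#' @param path PNG path.
#' @param meters_per_pixel,origin image geometry.
#' @return a [ppi_image()].
#' @export
read_ppi_png <- function(path, meters_per_pixel = 3.027, origin) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3) g <- g[, , 1]
  ppi_image(floor(round(g * 255) / 8), meters_per_pixel, origin)
}

#' Write a PPI image as an 8-bit grayscale PNG (gray = level * 8)
#'
#' @param image a [ppi_image()].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_ppi_png <- function(image, path) {
  stopifnot(inherits(image, "ppi_image"))
  png::writePNG(image$levels * 8 / 255, path)
  invisible(path)
}

#' Write a visibility mask as a black/white PNG for inspection
#'
#' @param mask a [visibility_mask()].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "visibility_mask"))
  png::writePNG(mask$visible * 1.0, path)
  invisible(path)
}
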