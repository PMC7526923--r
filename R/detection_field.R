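# 2D received-power field over (distance, height) and the detection
# boundary extracted from it at the minimum detectable power. The simple
# mode is the bare link budget with the vertical gain pattern; the
# advanced mode additionally applies the squared knife-edge factor of a
# clutter shielding fence, which suppresses the ground region and
# modulates the field at high elevation angles.

#' Simulate the 2D received-power field
#'
#' For every (distance d, height h) grid cell the slant range
#' R = sqrt(d^2 + (h - h_R)^2) and elevation phi = atan2(h - h_R, d) are
#' measured from the antenna phase center at (0, h_R); the received power
#' is the radar equation evaluated with the pattern gain at phi. In
#' advanced mode (a fence geometry supplied) the power is multiplied by
#' the squared normalized knife-edge intensity for that cell.
#'
#' @param system a [radar_system()].
#' @param pattern an [antenna_pattern()].
#' @param sigma_m2 target RCS in m^2 (> 0).
#' @param geom optional [csf_geometry()]; supplying one switches to
#'   advanced mode. Its antenna height should match the system's.
#' @param distances_m distance grid in meters (default 5 m steps to
#'   1500 m); in advanced mode every distance must exceed the fence
#'   radius.
#' @param heights_m height grid in meters (default 1 m steps to 300 m).
#' @return an object of class `power_field`: list with `distances_m`,
#'   `heights_m`, `power_w` (matrix, rows = heights, cols = distances),
#'   `mode` and the generating settings.
#' @export
simulate_field <- function(system, pattern, sigma_m2, geom = NULL,
                           distances_m = seq(5, 1500, by = 5),
                           heights_m = seq(0, 300, by = 1)) {
  stopifnot(inherits(system, "radar_system"),
            inherits(pattern, "antenna_pattern"),
            sigma_m2 > 0, length(distances_m) > 0, length(heights_m) > 0)
  mode <- "simple"
  if (!is.null(geom)) {
    stopifnot(inherits(geom, "csf_geometry"))
    if (min(distances_m) <= geom$fence_radius_m) {
      stop("all grid distances must exceed the fence radius in advanced mode",
           call. = FALSE)
    }
    mode <- "advanced"
  }
  h_r <- system$antenna_height_m
  lam <- wavelength(system)
  dz <- outer(heights_m - h_r, distances_m, function(z, d) z)  # height offset
  dd <- outer(heights_m, distances_m, function(h, d) d)
  slant <- sqrt(dd^2 + dz^2)
  phi <- atan2(dz, dd) * 180 / pi
  # hold the gain at the pattern's edge value beyond the sampled span;
  # steep cells are tens of dB below peak there and never detectable
  span <- range(pattern$elevation_deg)
  phi <- pmin(pmax(phi, span[1]), span[2])
  gain <- matrix(gain_at(pattern, as.vector(phi)), nrow = length(heights_m))
  p <- received_power(system, sigma_m2, slant, gain)
  if (mode == "advanced") {
    v1 <- outer(heights_m, distances_m, function(h, d) {
      edge_fresnel_v(geom, d, h, lam)
    })
    p <- modified_received_power(p, knife_edge_intensity(v1))
  }
  structure(
    list(distances_m = distances_m, heights_m = heights_m, power_w = p,
         mode = mode, sigma_m2 = sigma_m2, geom = geom,
         antenna_height_m = h_r),
    class = "power_field"
  )
}

#' @export
print.power_field <- function(x, ...) {
  cat(sprintf(
    "<power_field> %s mode, %d x %d (height x distance) cells, sigma = %.3g cm^2\n",
    x$mode, length(x$heights_m), length(x$distances_m), m2_to_cm2(x$sigma_m2)))
  invisible(x)
}

#' Extract the detection boundary from a power field
#'
#' Per distance column, finds the maximal contiguous height intervals
#' where the received power is at or above the detection threshold. In
#' simple mode this yields a single interval starting at the ground; in
#' advanced mode the fence raises the lower boundary and the high-angle
#' fringes may split the column into several intervals.
#'
#' @param field a [simulate_field()] result.
#' @param pmin_w detection threshold (minimum detectable signal power) in
#'   watts.
#' @return an object of class `detection_boundary`: `distances_m`,
#'   `intervals` (per distance, a 2-column matrix of \[low, high\] in
#'   meters, zero rows when nothing is detectable) and `max_range_m` (the
#'   largest distance with a non-empty interval; 0 when empty everywhere).
#' @export
extract_boundary <- function(field, pmin_w) {
  stopifnot(inherits(field, "power_field"), pmin_w > 0)
  h <- field$heights_m
  intervals <- lapply(seq_along(field$distances_m), function(j) {
    ok <- field$power_w[, j] >= pmin_w
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- which(runs$values)
    if (length(keep) == 0) {
      return(matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("low_m", "high_m"))))
    }
    cbind(low_m = h[starts[keep]], high_m = h[ends[keep]])
  })
  nonempty <- vapply(intervals, nrow, integer(1)) > 0
  max_range <- if (any(nonempty)) max(field$distances_m[nonempty]) else 0
  structure(
    list(distances_m = field$distances_m, intervals = intervals,
         max_range_m = max_range, mode = field$mode),
    class = "detection_boundary"
  )
}

#' @export
print.detection_boundary <- function(x, ...) {
  cat(sprintf("<detection_boundary> %s mode, max range %.0f m\n",
              x$mode, x$max_range_m))
  invisible(x)
}

#' Detectable height extent at a distance
#'
#' Total vertical extent (sum of interval heights, high - low) that is
#' detectable at the grid column nearest to the query distance. Distances
#' beyond the maximum detection range return 0.
#'
#' @param boundary a [extract_boundary()] result.
#' @param distance_m query distance(s) in meters; vectorized.
#' @return detectable height extent(s) in meters.
#' @export
detection_height_at <- function(boundary, distance_m) {
  stopifnot(inherits(boundary, "detection_boundary"))
  vapply(distance_m, function(d) {
    if (d > boundary$max_range_m) return(0)
    j <- which.min(abs(boundary$distances_m - d))
    iv <- boundary$intervals[[j]]
    if (nrow(iv) == 0) return(0)
    sum(iv[, "high_m"] - iv[, "low_m"])
  }, numeric(1))
}

#' Write a detection boundary as a character-separated table
#'
#' One row per (distance, interval): columns `distance_m`,
#' `interval_low_m`, `interval_high_m`.
#'
#' @param boundary a `detection_boundary`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_boundary <- function(boundary, path) {
  stopifnot(inherits(boundary, "detection_boundary"))
  rows <- do.call(rbind, lapply(seq_along(boundary$distances_m), function(j) {
    iv <- boundary$intervals[[j]]
    if (nrow(iv) == 0) return(NULL)
    data.frame(distance_m = boundary$distances_m[j],
               interval_low_m = iv[, "low_m"],
               interval_high_m = iv[, "high_m"])
  }))
  if (is.null(rows)) {
    rows <- data.frame(distance_m = numeric(0), interval_low_m = numeric(0),
                       interval_high_m = numeric(0))
  }
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a power field as a dBm matrix with axis headers
#'
#' Rows are heights, columns distances; the first column carries the
#' height grid and the header row the distance grid.
#'
#' @param field a `power_field`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "power_field"))
  m <- watts_to_dbm(pmax(field$power_w, .Machine$double.xmin))
  tab <- data.frame(height_m = field$heights_m, m, check.names = FALSE)
  names(tab) <- c("height_m", paste0("d", field$distances_m))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
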