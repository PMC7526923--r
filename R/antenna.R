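# Vertical antenna gain pattern G(phi). The manufacturer's measured
# diagram is typically unavailable, so the default is a parametric
# Gaussian main lobe (quadratic in dB) matching the published peak gain
# and -3 dB beamwidth of a marine slotted waveguide antenna.

#' Construct a tabulated vertical antenna pattern
#'
#' @param elevation_deg strictly increasing elevation angles in degrees;
#'   must span at least \[-30, +30\] so that detection-field simulations
#'   have pattern coverage over the angles that matter.
#' @param gain_dbi antenna gain in dBi at each elevation.
#' @return an object of class `antenna_pattern`. Gains are stored both in
#'   dB and as linear ratios; interpolation is linear in dB.
#' @export
antenna_pattern <- function(elevation_deg, gain_dbi) {
  stopifnot(length(elevation_deg) == length(gain_dbi),
            length(elevation_deg) >= 2)
  if (any(diff(elevation_deg) <= 0)) {
    stop("elevation_deg must be strictly increasing", call. = FALSE)
  }
  if (elevation_deg[1] > -30 || elevation_deg[length(elevation_deg)] < 30) {
    stop("pattern must span at least [-30, +30] degrees", call. = FALSE)
  }
  structure(
    list(elevation_deg = as.numeric(elevation_deg),
         gain_dbi = as.numeric(gain_dbi),
         peak_gain_linear = db_to_linear(max(gain_dbi))),
    class = "antenna_pattern"
  )
}

#' @export
print.antenna_pattern <- function(x, ...) {
  cat(sprintf("<antenna_pattern> %d samples over [%g, %g] deg, peak %.1f dBi\n",
              length(x$elevation_deg), min(x$elevation_deg),
              max(x$elevation_deg), max(x$gain_dbi)))
  invisible(x)
}

#' Parametric Gaussian main-lobe pattern
#'
#' G_dB(phi) = peak_dBi - 3 (phi / half_width)^2: a quadratic-in-dB main
#' lobe that is exactly 3 dB down at +/- `half_power_half_width_deg`.
#' Sampled on a 0.1 degree grid over +/- `span_deg`. Sidelobes are not
#' modelled.
#'
#' @param peak_gain_dbi boresight gain in dBi (default 31.6).
#' @param half_power_half_width_deg half width of the -3 dB region in
#'   degrees (default 10, typical of marine slotted waveguide antennas).
#' @param span_deg sampled half-span in degrees (default 45).
#' @return an `antenna_pattern`.
#' @examples
#' p <- gaussian_pattern()
#' linear_to_db(gain_at(p, 0))    # 31.6
#' linear_to_db(gain_at(p, 10))   # 28.6 (-3 dB)
#' @export
gaussian_pattern <- function(peak_gain_dbi = 31.6,
                             half_power_half_width_deg = 10,
                             span_deg = 45) {
  stopifnot(half_power_half_width_deg > 0, span_deg >= 30)
  phi <- seq(-span_deg, span_deg, by = 0.1)
  g_db <- peak_gain_dbi - 3 * (phi / half_power_half_width_deg)^2
  antenna_pattern(phi, g_db)
}

#' Interpolated gain towards an elevation angle
#'
#' Linear-in-dB interpolation between the bracketing pattern samples.
#'
#' @param pattern an [antenna_pattern()].
#' @param elevation_deg query elevation(s) in degrees; must lie within the
#'   sampled span.
#' @return linear gain ratio(s).
#' @export
gain_at <- function(pattern, elevation_deg) {
  stopifnot(inherits(pattern, "antenna_pattern"))
  rng <- range(pattern$elevation_deg)
  if (any(elevation_deg < rng[1] | elevation_deg > rng[2])) {
    stop("elevation outside the sampled span [", rng[1], ", ", rng[2], "] deg",
         call. = FALSE)
  }
  g_db <- stats::approx(pattern$elevation_deg, pattern$gain_dbi,
                        xout = elevation_deg, method = "linear")$y
  db_to_linear(g_db)
}

#' Read a tabulated antenna pattern from a text file
#'
#' Expects a two-column character-separated table with a header line:
#' elevation in degrees, gain in dBi.
#'
#' @param path file path.
#' @param sep field separator (default tab; any `read.table` separator).
#' @return an `antenna_pattern`.
#' @export
read_antenna_pattern <- function(path, sep = "") {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(tab) < 2) stop("pattern file needs two columns", call. = FALSE)
  antenna_pattern(tab[[1]], tab[[2]])
}

#' Write a tabulated antenna pattern to a text file
#'
#' @param pattern an [antenna_pattern()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_antenna_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "antenna_pattern"))
  tab <- data.frame(elevation_deg = pattern$elevation_deg,
                    gain_dbi = pattern$gain_dbi)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
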