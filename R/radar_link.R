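# Radar-equation link budget: the relationships between transmit power,
# antenna gain, wavelength, target RCS, range and received power for a
# monostatic pulse radar. All system losses are folded into the minimum
# detectable signal power P_min, which is recovered by calibration against
# a target of known RCS rather than derived from a receiver noise model.

#' Construct a radar system description
#'
#' Bundles the transmitter and antenna constants of a monostatic pulse
#' radar. Gains may be given in dBi or as a linear ratio; internally the
#' linear ratio is stored. The minimum detectable signal power is optional
#' at construction and is usually filled in later by calibration against a
#' reference sphere (see [calibrate_pmin()]).
#'
#' Defaults describe a 12 kW X-band marine magnetron radar at 9410 MHz with
#' a 31.6 dBi slotted waveguide antenna, 0.07 us pulse, mounted 2 m above
#' ground.
#'
#' @param transmit_power_w peak transmitted pulse power P_t in watts.
#' @param frequency_hz carrier frequency f in Hz.
#' @param peak_gain_dbi peak antenna gain in dBi. Give either this or
#'   `peak_gain_linear`, not both.
#' @param peak_gain_linear peak antenna gain as a linear power ratio.
#' @param pulse_length_s transmitted pulse length tau in seconds.
#' @param prf_hz pulse repetition frequency in Hz. Metadata only: no link
#'   budget equation in this package uses it.
#' @param antenna_height_m height of the antenna phase center above ground
#'   in meters.
#' @param min_detectable_power_w minimum detectable signal power P_min in
#'   watts, or `NULL` until calibrated.
#' @param wavelength_override_m optional wavelength in meters to use in
#'   place of c/f, for sensitivity checks against rounded published
#'   wavelengths. `NULL` (the default) means derive from the frequency.
#' @return an object of class `radar_system`.
#' @examples
#' rs <- radar_system()
#' wavelength(rs)          # about 0.03186 m
#' range_resolution(rs)    # 10.5 m
#' @export
radar_system <- function(transmit_power_w = 12000,
                         frequency_hz = 9410e6,
                         peak_gain_dbi = 31.6,
                         peak_gain_linear = NULL,
                         pulse_length_s = 0.07e-6,
                         prf_hz = 3000,
                         antenna_height_m = 2,
                         min_detectable_power_w = NULL,
                         wavelength_override_m = NULL) {
  if (!is.null(peak_gain_linear)) {
    gain <- peak_gain_linear
  } else {
    gain <- db_to_linear(peak_gain_dbi)
  }
  sys <- structure(
    list(
      transmit_power_w = transmit_power_w,
      frequency_hz = frequency_hz,
      peak_gain_linear = gain,
      pulse_length_s = pulse_length_s,
      prf_hz = prf_hz,
      antenna_height_m = antenna_height_m,
      min_detectable_power_w = min_detectable_power_w,
      wavelength_override_m = wavelength_override_m
    ),
    class = "radar_system"
  )
  validate_radar_system(sys)
}

validate_radar_system <- function(sys) {
  num_pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  for (f in c("transmit_power_w", "frequency_hz", "peak_gain_linear",
              "pulse_length_s", "prf_hz", "antenna_height_m")) {
    if (!num_pos(sys[[f]])) {
      stop("radar_system field '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (!is.null(sys$min_detectable_power_w)) {
    if (!num_pos(sys$min_detectable_power_w)) {
      stop("min_detectable_power_w must be a single positive number or NULL",
           call. = FALSE)
    }
    if (sys$min_detectable_power_w >= sys$transmit_power_w) {
      stop("min_detectable_power_w must be smaller than transmit_power_w",
           call. = FALSE)
    }
  }
  if (!is.null(sys$wavelength_override_m) && !num_pos(sys$wavelength_override_m)) {
    stop("wavelength_override_m must be a single positive number or NULL",
         call. = FALSE)
  }
  sys
}

#' @export
print.radar_system <- function(x, ...) {
  cat("<radar_system>\n")
  cat(sprintf("  transmit power : %g kW\n", x$transmit_power_w / 1e3))
  cat(sprintf("  frequency      : %g MHz (lambda = %.4f m%s)\n",
              x$frequency_hz / 1e6, wavelength(x),
              if (!is.null(x$wavelength_override_m)) ", overridden" else ""))
  cat(sprintf("  peak gain      : %.1f dBi\n", linear_to_db(x$peak_gain_linear)))
  cat(sprintf("  pulse length   : %g us (range resolution %.1f m)\n",
              x$pulse_length_s * 1e6, range_resolution(x)))
  cat(sprintf("  PRF            : %g Hz\n", x$prf_hz))
  cat(sprintf("  antenna height : %g m\n", x$antenna_height_m))
  if (is.null(x$min_detectable_power_w)) {
    cat("  P_min          : <uncalibrated>\n")
  } else {
    cat(sprintf("  P_min          : %.2f dBm\n",
                watts_to_dbm(x$min_detectable_power_w)))
  }
  invisible(x)
}

#' Operating wavelength of a radar system
#'
#' Returns c/f (c = 2.998e8 m/s) unless the system carries a wavelength
#' override, in which case the override is returned.
#'
#' @param system a [radar_system()].
#' @return wavelength in meters.
#' @export
wavelength <- function(system) {
  stopifnot(inherits(system, "radar_system"))
  if (!is.null(system$wavelength_override_m)) {
    return(system$wavelength_override_m)
  }
  speed_of_light() / system$frequency_hz
}

#' Theoretical range resolution of a pulse radar
#'
#' The two-way pulse-length limit c * tau / 2.
#'
#' @param system a [radar_system()].
#' @return range resolution in meters.
#' @export
range_resolution <- function(system) {
  stopifnot(inherits(system, "radar_system"))
  speed_of_light() * system$pulse_length_s / 2
}

#' Received signal power from a point target
#'
#' Monostatic radar equation solved for the received power:
#' P_r = P_t g^2 lambda^2 sigma / (R^4 (4 pi)^3). The gain defaults to the
#' system's peak gain; pass the off-boresight gain explicitly when
#' evaluating away from the beam axis.
#'
#' @param system a [radar_system()].
#' @param sigma_m2 target radar cross section in m^2 (>= 0); vectorized.
#' @param range_m target range in meters (> 0); vectorized.
#' @param gain_linear antenna gain towards the target as a linear ratio;
#'   defaults to the system's peak gain.
#' @return received power in watts.
#' @export
received_power <- function(system, sigma_m2, range_m,
                           gain_linear = system$peak_gain_linear) {
  stopifnot(inherits(system, "radar_system"))
  if (any(range_m <= 0)) stop("range_m must be > 0", call. = FALSE)
  if (any(sigma_m2 < 0)) stop("sigma_m2 must be >= 0", call. = FALSE)
  lam <- wavelength(system)
  system$transmit_power_w * gain_linear^2 * lam^2 * sigma_m2 /
    (range_m^4 * (4 * pi)^3)
}

#' Maximum detection range for a target of given RCS
#'
#' Radar equation solved for range at the minimum detectable signal power:
#' R_max = (P_t g^2 lambda^2 sigma / ((4 pi)^3 P_min))^(1/4).
#'
#' @param system a calibrated [radar_system()] (P_min set).
#' @param sigma_m2 target RCS in m^2 (> 0); vectorized.
#' @return maximum detection range in meters.
#' @export
max_detection_range <- function(system, sigma_m2) {
  stopifnot(inherits(system, "radar_system"))
  pmin_w <- require_pmin(system)
  if (any(sigma_m2 <= 0)) stop("sigma_m2 must be > 0", call. = FALSE)
  lam <- wavelength(system)
  (system$transmit_power_w * system$peak_gain_linear^2 * lam^2 * sigma_m2 /
    ((4 * pi)^3 * pmin_w))^(1 / 4)
}

#' RCS implied by a measured maximum detection range
#'
#' Radar equation solved for the cross section:
#' sigma = R_max^4 (4 pi)^3 P_min / (P_t g^2 lambda^2). This is how the
#' RCS of a field target is recovered from its observed maximum range once
#' the system is calibrated.
#'
#' @param system a calibrated [radar_system()] (P_min set).
#' @param r_max_m measured maximum detection range in meters (> 0);
#'   vectorized.
#' @return RCS in m^2.
#' @export
rcs_from_range <- function(system, r_max_m) {
  stopifnot(inherits(system, "radar_system"))
  pmin_w <- require_pmin(system)
  if (any(r_max_m <= 0)) stop("r_max_m must be > 0", call. = FALSE)
  lam <- wavelength(system)
  r_max_m^4 * (4 * pi)^3 * pmin_w /
    (system$transmit_power_w * system$peak_gain_linear^2 * lam^2)
}

#' Minimum detectable power implied by a reference target
#'
#' Radar equation solved for P_min at the maximum range of a target with
#' known RCS: P_min = P_t g^2 lambda^2 sigma / ((4 pi)^3 R_max^4). This is
#' the calibration step: with a reference sphere of known cross section,
#' the measured maximum range fixes P_min, which then absorbs every system
#' loss.
#'
#' @param system a [radar_system()] (P_min need not be set).
#' @param r_max_m measured maximum detection range of the reference target
#'   in meters (> 0).
#' @param sigma_m2 known RCS of the reference target in m^2 (> 0). A zero
#'   RCS is degenerate and rejected.
#' @return minimum detectable signal power in watts.
#' @export
pmin_from_range <- function(system, r_max_m, sigma_m2) {
  stopifnot(inherits(system, "radar_system"))
  if (any(r_max_m <= 0)) stop("r_max_m must be > 0", call. = FALSE)
  if (any(sigma_m2 <= 0)) {
    stop("sigma_m2 must be > 0 (a zero-RCS reference cannot calibrate P_min)",
         call. = FALSE)
  }
  lam <- wavelength(system)
  system$transmit_power_w * system$peak_gain_linear^2 * lam^2 * sigma_m2 /
    ((4 * pi)^3 * r_max_m^4)
}

#' Calibrate a radar system against a reference target
#'
#' Convenience wrapper: computes [pmin_from_range()] and returns a copy of
#' the system with its minimum detectable power set.
#'
#' @inheritParams pmin_from_range
#' @return the system with `min_detectable_power_w` filled in.
#' @examples
#' rs <- radar_system()
#' sphere <- mie_pec_rcs(0.005, wavelength(rs))
#' rs <- calibrate_pmin(rs, r_max_m = 550, sigma_m2 = sphere$sigma_m2)
#' watts_to_dbm(rs$min_detectable_power_w)  # about -74 dBm
#' @export
calibrate_pmin <- function(system, r_max_m, sigma_m2) {
  system$min_detectable_power_w <- pmin_from_range(system, r_max_m, sigma_m2)
  validate_radar_system(system)
}

require_pmin <- function(system) {
  if (is.null(system$min_detectable_power_w)) {
    stop("radar system is not calibrated: min_detectable_power_w is unset; ",
         "use calibrate_pmin() or set it directly", call. = FALSE)
  }
  system$min_detectable_power_w
}
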