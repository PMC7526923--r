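# YAML serialization of the configurable objects. Keys mirror the names
# used on a radar data sheet (pulse power, frequency, antenna gain, pulse
# length, PRF) so a config file reads like the system's specification
# table. RCS values are written in cm^2 (the reporting unit) and powers
# in dBm at this interface; everything is converted to SI on read.

#' Write a radar system to a YAML config file
#'
#' @param system a [radar_system()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_radar_config <- function(system, path) {
  stopifnot(inherits(system, "radar_system"))
  cfg <- list(
    pulse_power_kw = system$transmit_power_w / 1e3,
    frequency_mhz = system$frequency_hz / 1e6,
    antenna_gain_dbi = linear_to_db(system$peak_gain_linear),
    pulse_length_us = system$pulse_length_s * 1e6,
    prf_hz = system$prf_hz,
    antenna_height_m = system$antenna_height_m
  )
  if (!is.null(system$min_detectable_power_w)) {
    cfg$min_detectable_power_dbm <- watts_to_dbm(system$min_detectable_power_w)
  }
  if (!is.null(system$wavelength_override_m)) {
    cfg$wavelength_override_m <- system$wavelength_override_m
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a radar system from a YAML config file
#'
#' @param path file path written by [write_radar_config()] (or
#'   hand-written with the same keys).
#' @return a [radar_system()].
#' @export
read_radar_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("pulse_power_kw", "frequency_mhz", "antenna_gain_dbi",
             "pulse_length_us", "prf_hz", "antenna_height_m",
             "min_detectable_power_dbm", "wavelength_override_m")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown radar config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  radar_system(
    transmit_power_w = cfg$pulse_power_kw * 1e3,
    frequency_hz = cfg$frequency_mhz * 1e6,
    peak_gain_dbi = cfg$antenna_gain_dbi,
    pulse_length_s = cfg$pulse_length_us * 1e-6,
    prf_hz = if (is.null(cfg$prf_hz)) 3000 else cfg$prf_hz,
    antenna_height_m = if (is.null(cfg$antenna_height_m)) 2
                       else cfg$antenna_height_m,
    min_detectable_power_w = if (is.null(cfg$min_detectable_power_dbm)) NULL
                             else dbm_to_watts(cfg$min_detectable_power_dbm),
    wavelength_override_m = cfg$wavelength_override_m
  )
}

#' Write a fence geometry to a YAML config file
#'
#' @param geom a [csf_geometry()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_csf_config <- function(geom, path) {
  stopifnot(inherits(geom, "csf_geometry"))
  yaml::write_yaml(
    list(fence_height_m = geom$fence_height_m,
         fence_radius_m = geom$fence_radius_m,
         antenna_height_m = geom$antenna_height_m),
    path)
  invisible(path)
}

#' Read a fence geometry from a YAML config file
#'
#' @param path file path.
#' @return a [csf_geometry()].
#' @export
read_csf_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg),
                     c("fence_height_m", "fence_radius_m", "antenna_height_m"))
  if (length(unknown) > 0) {
    stop("unknown CSF config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  csf_geometry(cfg$fence_height_m, cfg$fence_radius_m, cfg$antenna_height_m)
}

#' Write a scene spec to a YAML config file
#'
#' @param spec a [scene_spec()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scene_config <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  yaml::write_yaml(
    list(size_px = spec$size_px, meters_per_pixel = spec$meters_per_pixel,
         origin_row = spec$origin[1], origin_col = spec$origin[2],
         seed = spec$seed,
         clutter_blobs = lapply(spec$clutter_blobs, function(b) {
           list(center_row = b$center[1], center_col = b$center[2],
                radius_px = b$radius_px, base_level = b$base_level,
                fluctuation_amplitude = b$fluctuation_amplitude)
         }),
         point_echoes = lapply(spec$point_echoes, function(e) {
           list(bearing_deg = e$bearing_deg, range_m = e$range_m,
                mean_level = e$mean_level,
                fluctuation_amplitude = e$fluctuation_amplitude)
         })),
    path)
  invisible(path)
}

#' Read a scene spec from a YAML config file
#'
#' @param path file path.
#' @return a [scene_spec()].
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  scene_spec(
    size_px = cfg$size_px,
    meters_per_pixel = cfg$meters_per_pixel,
    origin = c(cfg$origin_row, cfg$origin_col),
    clutter_blobs = lapply(cfg$clutter_blobs, function(b) {
      list(center = c(b$center_row, b$center_col), radius_px = b$radius_px,
           base_level = b$base_level,
           fluctuation_amplitude = b$fluctuation_amplitude)
    }),
    point_echoes = cfg$point_echoes,
    seed = cfg$seed
  )
}
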