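# 3D detection-volume integration: each horizontally visible pixel
# contributes its ground area times the vertical detectable extent at its
# distance, V = sum_p A_px h(d_p). On top of that: extrapolation of a
# sector volume to full-circle operation, the hemispherical acoustic
# detector comparison, and the fence-height x clutter-threshold
# optimization sweep.

#' Integrate the 3D detection volume over a visibility mask
#'
#' V = sum over visible pixels of A_px * h(d_p), with h(d) the detectable
#' height extent from the detection boundary at the pixel's
#' center-to-center distance. Pixels beyond the boundary's maximum range
#' contribute nothing.
#'
#' @param mask a [visibility_mask()].
#' @param boundary a [extract_boundary()] result computed under the same
#'   radar settings.
#' @return an object of class `volume_result`: `total_volume_m3`,
#'   `visible_pixel_count` (n), `pixel_area_m2` and the sector.
#' @export
integrate_volume <- function(mask, boundary) {
  stopifnot(inherits(mask, "visibility_mask"),
            inherits(boundary, "detection_boundary"))
  a_px <- pixel_area(mask$meters_per_pixel)
  d <- mask$distance_m[mask$visible]
  h <- detection_height_at(boundary, d)
  structure(
    list(total_volume_m3 = a_px * sum(h),
         visible_pixel_count = length(d),
         pixel_area_m2 = a_px,
         sector = mask$sector,
         clutter_threshold = mask$clutter_threshold,
         mode = boundary$mode),
    class = "volume_result"
  )
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf(
    "<volume_result> V = %.4g m^3 (%.4g km^3) from %d visible pixels (%s mode)\n",
    x$total_volume_m3, x$total_volume_m3 / 1e9, x$visible_pixel_count, x$mode))
  invisible(x)
}

#' Extrapolate a sector volume to a wider angular coverage
#'
#' Linear in angle: V * target / sector.
#'
#' @param volume_m3 sector volume in m^3, or a `volume_result`.
#' @param sector_angle_deg angular width of the measured sector in
#'   degrees (> 0); taken from the result when one is given.
#' @param target_angle_deg target angular coverage (default 360).
#' @return extrapolated volume in m^3.
#' @export
sector_extrapolate <- function(volume_m3, sector_angle_deg = NULL,
                               target_angle_deg = 360) {
  if (inherits(volume_m3, "volume_result")) {
    if (is.null(sector_angle_deg)) {
      sector_angle_deg <- sector_angle(volume_m3$sector)
    }
    volume_m3 <- volume_m3$total_volume_m3
  }
  if (is.null(sector_angle_deg) || sector_angle_deg <= 0) {
    stop("sector_angle_deg must be > 0", call. = FALSE)
  }
  volume_m3 * target_angle_deg / sector_angle_deg
}

#' Detection volume of a hemispherical acoustic detector
#'
#' (2/3) pi r^3: the airspace covered by a microphone with a
#' hemispherical detection characteristic of the given radius.
#'
#' @param radius_m microphone detection radius in meters (default 40).
#' @return volume in m^3.
#' @export
acoustic_hemisphere_volume <- function(radius_m = 40) {
  stopifnot(radius_m > 0)
  2 / 3 * pi * radius_m^3
}

#' Radar-to-acoustic detection volume ratio
#'
#' Extrapolates the radar sector volume to 360 degrees and divides by the
#' hemispherical acoustic detector volume.
#'
#' @param sector_volume_m3 radar sector volume in m^3.
#' @param sector_angle_deg sector angular width in degrees.
#' @param mic_radius_m acoustic detector radius in meters (default 40).
#' @return list with `ratio` (raw) and `ratio_rounded` (nearest ten).
#' @examples
#' volume_ratio_vs_acoustic(0.0105e9, 105)  # ~268.6, rounds to 270
#' @export
volume_ratio_vs_acoustic <- function(sector_volume_m3, sector_angle_deg,
                                     mic_radius_m = 40) {
  stopifnot(sector_volume_m3 > 0, sector_angle_deg > 0, mic_radius_m > 0)
  r <- sector_extrapolate(sector_volume_m3, sector_angle_deg, 360) /
    acoustic_hemisphere_volume(mic_radius_m)
  list(ratio = r, ratio_rounded = round(r / 10) * 10)
}

#' Fence-height x clutter-threshold optimization sweep
#'
#' For every combination of fence-to-antenna height difference h_CFR and
#' clutter threshold, computes the detection volume with and without the
#' fence and their ratio. The fence template fixes the fence height and
#' radius; each h_CFR value is realized by adjusting the antenna height
#' (h_R = h_CF - h_CFR), as in a field setup where the fence stands and
#' the antenna mast is raised or lowered. The without-fence member uses
#' the simple power field and the supplied image; the with-fence member
#' uses the advanced field and a paired image whose clutter is attenuated
#' by the fence's two-way suppression (see [render_csf_pair()]).
#'
#' @param system a calibrated [radar_system()].
#' @param pattern an [antenna_pattern()].
#' @param sigma_m2 target RCS in m^2.
#' @param image a [ppi_image()] captured (or synthesized) without a
#'   fence. Must carry a clutter mask attribute (as produced by
#'   [render_scene()]) or `clutter_mask` must be given.
#' @param sector a [sector_spec()].
#' @param fence_template a [csf_geometry()] giving the fence height and
#'   radius; its antenna height is overridden per h_CFR value.
#' @param h_cfr_values_m sequence of height differences h_CFR in meters.
#' @param thresholds sequence of clutter thresholds (levels 0-31).
#' @param clutter_mask optional logical matrix marking clutter pixels in
#'   `image`.
#' @param distances_m,heights_m simulation grids for
#'   [simulate_field()].
#' @param level_step_db dB represented by one intensity level when
#'   attenuating clutter in the paired image (default 3).
#' @return data frame with columns `h_cfr_m`, `threshold`,
#'   `volume_no_csf_m3`, `volume_csf_m3`, `ratio`.
#' @export
optimization_sweep <- function(system, pattern, sigma_m2, image, sector,
                               fence_template, h_cfr_values_m, thresholds,
                               clutter_mask = NULL,
                               distances_m = seq(10, 1500, by = 10),
                               heights_m = seq(0, 300, by = 2),
                               level_step_db = 3) {
  stopifnot(inherits(image, "ppi_image"), length(h_cfr_values_m) > 0,
            length(thresholds) > 0)
  pmin_w <- require_pmin(system)
  if (is.null(clutter_mask)) clutter_mask <- attr(image, "clutter_mask")
  simple_field <- simulate_field(system, pattern, sigma_m2, NULL,
                                 distances_m, heights_m)
  simple_boundary <- extract_boundary(simple_field, pmin_w)
  out <- list()
  for (h_cfr in h_cfr_values_m) {
    geom <- csf_geometry(
      fence_height_m = fence_template$fence_height_m,
      fence_radius_m = fence_template$fence_radius_m,
      antenna_height_m = fence_template$fence_height_m - h_cfr
    )
    sys_h <- system
    sys_h$antenna_height_m <- geom$antenna_height_m
    adv_field <- simulate_field(sys_h, pattern, sigma_m2, geom,
                                distances_m, heights_m)
    adv_boundary <- extract_boundary(adv_field, pmin_w)
    pair <- render_csf_pair_image(image, geom, wavelength(system),
                                  clutter_mask, level_step_db)
    for (thr in thresholds) {
      v_no <- integrate_volume(visibility_mask(image, sector, thr),
                               simple_boundary)
      v_with <- integrate_volume(visibility_mask(pair, sector, thr),
                                 adv_boundary)
      out[[length(out) + 1]] <- data.frame(
        h_cfr_m = h_cfr, threshold = thr,
        volume_no_csf_m3 = v_no$total_volume_m3,
        volume_csf_m3 = v_with$total_volume_m3,
        ratio = if (v_no$total_volume_m3 > 0) {
          v_with$total_volume_m3 / v_no$total_volume_m3
        } else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Write an optimization sweep table plus JSON summary
#'
#' @param sweep data frame from [optimization_sweep()].
#' @param path path for the character-separated table; a JSON summary
#'   (best row by with-fence volume) goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(sweep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  best <- sweep[which.max(sweep$volume_csf_m3), ]
  jsonlite::write_json(
    list(best_h_cfr_m = best$h_cfr_m, best_threshold = best$threshold,
         best_volume_csf_m3 = best$volume_csf_m3,
         best_volume_csf_km3 = best$volume_csf_m3 / 1e9,
         ratio = best$ratio),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
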