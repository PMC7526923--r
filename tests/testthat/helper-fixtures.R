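# Shared fixtures. The default system is the study configuration:
# 12 kW / 9410 MHz / 31.6 dBi / 0.07 us, antenna 2 m above ground,
# calibrated against the 1 cm conducting sphere observed out to 550 m.

default_system <- function() radar_system()

calibrated_system <- function() {
  sys <- radar_system()
  sphere <- mie_pec_rcs(0.005, wavelength(sys))
  calibrate_pmin(sys, r_max_m = 550, sigma_m2 = sphere$sigma_m2)
}

study_fence <- function() csf_geometry(fence_height_m = 2.2,
                                       fence_radius_m = 6,
                                       antenna_height_m = 2)

# Flat (isotropic) pattern at a given dBi gain, for closed-form checks.
isotropic_pattern <- function(gain_dbi) {
  antenna_pattern(c(-45, 45), c(gain_dbi, gain_dbi))
}

# Independent spherical Bessel routes for the Mie oracle: power series
# for j_n (fast convergence at the small size parameters under test) and
# the closed-form-seeded upward recurrence for y_n (stable upward).
oracle_sph_j <- function(n, x) {
  total <- 0
  term <- 1
  k <- 0
  repeat {
    total <- total + term
    k <- k + 1
    term <- term * (-x^2 / 2) / (k * (2 * n + 2 * k + 1))
    if (abs(term) < 1e-18 * abs(total)) break
    if (k > 200) break
  }
  x^n / prod(seq(1, 2 * n + 1, by = 2)) * total
}

oracle_sph_y <- function(n, x) {
  y0 <- -cos(x) / x
  if (n == 0) return(y0)
  y1 <- -cos(x) / x^2 - sin(x) / x
  if (n == 1) return(y1)
  for (k in 2:n) {
    y2 <- (2 * k - 1) / x * y1 - y0
    y0 <- y1
    y1 <- y2
  }
  y1
}

# Independent PEC Mie backscatter oracle built on the routes above.
oracle_mie_pec <- function(radius_m, wavelength_m, n_max = 40) {
  x <- 2 * pi * radius_m / wavelength_m
  s <- 0 + 0i
  for (n in seq_len(n_max)) {
    jn <- oracle_sph_j(n, x); yn <- oracle_sph_y(n, x)
    jn1 <- oracle_sph_j(n - 1, x); yn1 <- oracle_sph_y(n - 1, x)
    hn <- complex(real = jn, imaginary = yn)
    hn1 <- complex(real = jn1, imaginary = yn1)
    an <- jn / hn
    bn <- (x * jn1 - n * jn) / (x * hn1 - n * hn)
    s <- s + (-1)^n * (2 * n + 1) * (bn - an)
  }
  wavelength_m^2 / (4 * pi) * Mod(s)^2
}

# Quadrature oracle for the Fresnel integrals.
oracle_fresnel <- function(v) {
  list(
    C = stats::integrate(function(t) cos(pi * t^2 / 2), 0, v,
                         rel.tol = 1e-12)$value,
    S = stats::integrate(function(t) sin(pi * t^2 / 2), 0, v,
                         rel.tol = 1e-12)$value
  )
}

# A small cluttered scene with one clean point echo, used across the
# image/volume tests.
demo_scene <- function(seed = 7) {
  scene_spec(
    size_px = 128,
    clutter_blobs = list(
      list(center = c(40, 80), radius_px = 10, base_level = 14,
           fluctuation_amplitude = 2)),
    point_echoes = list(
      list(bearing_deg = 45, range_m = 120, mean_level = 31,
           fluctuation_amplitude = 0)),
    seed = seed
  )
}
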