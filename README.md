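# batradar

Spatial detection-volume modelling for monitoring bats (and other small
airborne targets) with an ordinary X-band marine pulse radar in onshore
wind parks.

Acoustic bat detectors reach a few tens of meters; a marine radar reaches
hundreds. But radar observations are only comparable between sites and
studies if the instrument is calibrated — i.e. if one can state *which
volume of airspace* a bat-sized echo could have come from. That volume is
shaped by three things: the radar link budget, the vertical antenna
pattern, and the ground clutter of the individual site (plus, optionally,
a clutter shielding fence built around the antenna). `batradar`
implements the full analytical chain:

1. **Link budget and calibration** (`radar_system()`, `calibrate_pmin()`,
   `rcs_from_range()`): the monostatic radar equation

   R_max = ( P_t G² λ² σ / ((4π)³ P_min) )^¼

   is solved in all directions. The minimum detectable signal power
   P_min — which absorbs every system loss — is recovered from the
   measured maximum detection range of a conducting reference sphere
   whose radar cross section σ is computed exactly with the **Mie
   series** (`mie_pec_rcs()`). With P_min fixed, the measured maximum
   range of any field target yields its RCS.

2. **RCS models for small animals** (`water_sphere_rcs()`,
   `optical_sphere_rcs()`): the water-sphere simplification from radar
   ornithology (σ = k π r², k = 0.56 for water) and a dielectric-sphere
   Mie evaluation with a Debye water permittivity.

3. **Fence diffraction** (`csf_geometry()`, `knife_edge_intensity()`,
   `one_way_suppression_db()`): a clutter shielding fence (CSF) around
   the antenna suppresses ground clutter; its effect on the field is the
   Fresnel sharp-edge (knife-edge) diffraction of the fence's upper
   edge, I_P/I₀ = ½[(½−C(v₁))² + (½−S(v₁))²], applied twice (transmit
   and receive): P_rm = P_r (I_P/I₀)².

4. **2D detection boundary** (`simulate_field()`, `extract_boundary()`):
   received power over a (distance × height) grid with the vertical gain
   pattern, thresholded at P_min, with or without the fence.

5. **Horizontal visibility and echo analysis** (`ppi_image()`,
   `visibility_mask()`, `echo_matrix_mean()`, `stack_visibility()`):
   clutter-threshold masks on 32-level quantized PPI images, and the
   conservative multi-frame visibility rule used for the calibration
   experiments (3×3 matrix mean ≥ level 25 in more than 5 of 11
   consecutive scans).

6. **3D volume** (`integrate_volume()`, `optimization_sweep()`,
   `volume_ratio_vs_acoustic()`): every horizontally visible pixel
   contributes its ground area times the vertical detectable extent at
   its distance, V = Σₚ A_px h(d_p); sweeps over fence height and
   clutter threshold locate the largest detection volume, and the result
   can be compared against a hemispherical acoustic detector.

A seeded synthetic scene generator (`scene_spec()`, `render_scene()`,
`render_stack()`, `render_csf_pair()`) produces quantized PPI images with
fluctuating clutter and point echoes so the entire pipeline runs and is
tested without any field data.

## Worked example: calibrating and sizing the detection space

```r
library(batradar)

rs <- radar_system()                      # 12 kW, 9410 MHz, 31.6 dBi, 0.07 us
sphere <- mie_pec_rcs(0.005, wavelength(rs))
m2_to_cm2(sphere$sigma_m2)                # 2.84 cm^2 reference sphere

rs <- calibrate_pmin(rs, r_max_m = 550, sigma_m2 = sphere$sigma_m2)
rs
#> <radar_system>
#>   transmit power : 12 kW
#>   frequency      : 9410 MHz (lambda = 0.0319 m)
#>   peak gain      : 31.6 dBi
#>   pulse length   : 0.07 us (range resolution 10.5 m)
#>   PRF            : 3000 Hz
#>   antenna height : 2 m
#>   P_min          : -74.00 dBm

m2_to_cm2(rcs_from_range(rs, 800))        # 12.7 cm^2 for a bat-sized target
```

The sphere, observed out to 550 m, pins P_min at −74 dBm; a bat model
observed out to 800 m then has an average RCS of 12.7 cm². The vertical
detection boundary for that target:

```r
pat <- gaussian_pattern()                 # 31.6 dBi, +/-10 deg at -3 dB
field <- simulate_field(rs, pat, cm2_to_m2(12.7))
boundary <- extract_boundary(field, rs$min_detectable_power_w)
boundary
#> <detection_boundary> simple mode, max range 795 m
detection_height_at(boundary, 400)        # 100 m of detectable air column
```

(The 795 m reflects the 5 m distance grid and the 12.7 cm² input being
the rounded calibration value.) The fence's one-way suppression of the
ground region, in dB:

```r
fence <- csf_geometry(fence_height_m = 2.2, fence_radius_m = 6,
                      antenna_height_m = 2)
round(one_way_suppression_db(fence, c(0, 1, 2), c(50, 200, 1000),
                             wavelength(rs)), 1)
#>         distance_m
#> height_m   50  200 1000
#>        0 16.9 12.9 11.7
#>        1 14.5 12.2 11.5
#>        2 11.7 11.4 11.4
```

Everything 0–2 m above ground is shielded by more than 10 dB one-way
(over 20 dB two-way) at all distances. Combining a visibility mask of a
PPI image with the boundary gives the 3D volume; see the vignette in
`vignettes/` for the full pipeline including the fence-height ×
clutter-threshold sweep on synthetic scenes.

A thin command-line wrapper over the same functions is installed at
`inst/cli/batradar` (subcommands `calibrate-pmin`, `calibrate-rcs`,
`detection-range`, `visibility`, `echo-stack`, `volume`, `sweep`,
`synth`).

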