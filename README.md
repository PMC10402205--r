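# ulmpact

Spherical-array photoacoustic computed tomography (PACT) and 3D ultrasound
localization microscopy (ULM), implemented end to end in R at desk scale.

Dual-mode brain imaging systems built around a spherical-cap transducer
array acquire two complementary views of the vasculature: multi-wavelength
photoacoustic volumes, unmixed into haemoglobin oxygen saturation (sO2),
and high-frame-rate synthetic-aperture ultrasound, processed into
super-resolved microbubble density and flow-velocity maps. `ulmpact`
implements the full computational chain of such a system — plus an analytic
acoustic simulator that stands in for the scanner — so every stage is
testable on a workstation:

* **Array model** — quasi-uniform spherical-cap element layouts, maximin
  transmit subsets, acquisition arithmetic (31 transmissions at 150 µs →
  215 Hz volume rate; 3×2 raster scan at 3 mm → 14×11×8 mm³ stitched FOV).
* **Forward simulation** — point photoacoustic sources (one-way, spherical
  spreading), pulse-echo scatterers (two-way), flowing microbubbles, static
  clutter, Gaussian-pulse impulse responses, band-limited fractional
  delays, seeded noise.
* **Beamforming** — 3D delay-and-sum for PA (signed or envelope) and
  synthetic-aperture US (complex IQ via the analytic signal), a sparse
  matrix DAS operator equivalent to the direct sums to 1e-6, Wiener
  impulse-response deconvolution, zero-phase 1 MHz low-pass, multi-position
  stitching.
* **Spectral unmixing** — per-voxel 2×2 linear solve for HbO2/HbR at
  700/750 nm, `sO2 = C_HbO2/(C_HbO2+C_Hb)`, scale-invariant (no fluence
  compensation), invalid voxels flagged.
* **ULM** — MIP-correlation motion gating (99% threshold), spatiotemporal
  SVD clutter filtering (600-frame blocks, 150 components), 20–107 Hz
  slow-time band-pass, directional filtering, power Doppler, 3D
  radial-symmetry sub-voxel localization, Hungarian-assignment tracking
  with gap closing, and 4× super-resolved density/velocity rendering.
* **Quantification** — morphological vessel segmentation with
  distance-transform radii and geodesic centerlines, per-vessel sO2/speed
  extraction, hemisphere group statistics with the two-sample Z-test,
  FWHM and kernel-density utilities.
* **Pipeline** — a schema-validated config drives
  simulate → beamform → sO2/ULM → quantify reproducibly (per-stage seeds
  derived from one global seed; bit-identical reruns).

Localizations, tracks and vessel records are tibbles that flow through
dplyr, with `tidy()`/`glance()` summaries and `autoplot()` methods; RF data
and volumes are lightweight array containers with NIfTI/CSV/JSON
persistence.

## Worked example

Acquisition arithmetic and the published group comparison:

```r
library(ulmpact)

volumetric_frame_rate(31, 150e-6)
#> [1] 215.0538
stitched_fov(scan_grid(3, 2, 3, c(8, 8, 8)))
#>  x  y  z
#> 14 11  8

two_sample_z(list(mean = 5.198, sd = 1.266, n = 219),   # healthy speeds
             list(mean = 4.577, sd = 1.296, n = 134))   # stroke speeds
#>   difference     z         p
#> 1      0.621  4.41 0.0000105
```

The 0.621 mm/s flow-speed difference between hemispheres is highly
significant (Z = 4.41 from the printed summaries; the published rounded
figure is 4.43).

Simulated system resolution — a noiseless point source at the focus of the
256-element, 40 mm / 57 mm cap, reconstructed at 60 µm voxels:

```r
psf_resolution(grid = voxel_grid(c(61, 9, 41), 0.06))
#>   lateral_fwhm_um axial_fwhm_um
#> 1            267.          361.
```

267 µm lateral, against the 260 µm measured on the physical system.

A miniature ULM pass — one bubble at 5 mm/s, tracked and rendered at 4×
super-resolution:

```r
grid <- voxel_grid(c(24, 24, 12), 0.1)          # 100 µm voxels
locs <- lapply(1:40, function(f)
  tibble::tibble(x = -1 + f * 5 / 215, y = 0.25, z = 0.15,
                 frame = f, intensity = 1))
tracks <- track_bubbles(locs, frame_rate = 215, max_link = 0.1,
                        min_length = 5)
glance(tracks)
#>   n_tracks n_points mean_speed_mms frame_rate
#> 1        1       40              5        215

maps <- render_maps(tracks, grid, upsample = 4)
mean(maps$velocity$data, na.rm = TRUE)
#> [1] 5
```

The velocity map reads the ground-truth 5 mm/s on the track's support, on a
25 µm rendering grid.

The full demo — two vessels with different oxygenations, flowing bubbles,
clutter, 200 frames — runs from one config:

```r
run_pipeline(default_config(seed = 1), "demo_run")
# demo_run/ now holds RF, IQ series, B-mode, PD, sO2, density, velocity,
# tracks.csv, vessels.csv, config.json, checksums.json
```

A command-line wrapper lives at `inst/cli/ulmpact.R`
(`ulmpact.R run --seed 1 --out-dir demo_run`).

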