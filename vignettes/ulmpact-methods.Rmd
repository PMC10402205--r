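---
title: "Methods: spherical-array PACT and 3D ultrasound localization microscopy in ulmpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spherical-array PACT and 3D ULM in ulmpact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ulmpact` is a desk-scale computational counterpart of a dual-mode brain
imaging system: volumetric photoacoustic computed tomography (PACT) and
ultrasound localization microscopy (ULM) acquired through one spherical-cap
transducer array. This vignette explains the models the package implements,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was open.

## The system being modelled

The array is a spherical cap of 256 elements with a 40 mm radius of
curvature and a 57 mm total aperture, centred at 4 MHz with a 75% receive
(-6 dB) bandwidth. All coordinates are metric millimetres in a frame centred
on the geometric focus, with +z pointing away from the array. Photoacoustic
excitation arrives at 700, 750 or 1064 nm; RF is sampled at 20.83 MHz.
Ultrasound imaging is synthetic-aperture: 31 single-element transmissions
spaced 150 microseconds apart give a 215 Hz volumetric frame rate
(`volumetric_frame_rate(31, 150e-6)`), received on the full 256-element
aperture. Raster scanning on a 3 x 2 lattice with a 3 mm step extends the
8 x 8 x 8 mm focal zone to a stitched 14 x 11 x 8 mm field of view
(`stitched_fov(scan_grid(3, 2, 3))`).

The exact tiling of elements on the physical cap is proprietary, so
`build_spherical_array()` places elements on a deterministic golden-angle
(Fibonacci) spiral with equal-area polar spacing. This is a documented
stand-in: point-spread behaviour is governed by the aperture, curvature and
bandwidth rather than the precise tiling, and the layout is reproducible
from its seed. Transmit subsets are chosen by farthest-point (maximin)
sampling, which reproduces the ~7.5 mm spacing between neighbouring
transmitters at 31 of 256 elements.

## The forward model (synthetic-data generator)

The generator replaces both the physical scanner and full-wave simulation
with analytic delay-amplitude propagation:

* **Photoacoustic.** A point absorber excited by an impulse contributes, on
  each element, the transducer impulse response delayed by the one-way time
  of flight and scaled by `absorbed_energy * spectrum(lambda) / r`
  (spherical spreading). The impulse response is a Gaussian-modulated
  sinusoid (`gaussian_pulse()`) whose -6 dB spectral width equals the
  fractional bandwidth by construction.
* **Ultrasound.** A point scatterer insonified by a single-element
  transmission contributes the pulse delayed by the two-way time of flight
  `(r_tx + r_rx) / c` and scaled by `echogenicity / (r_tx * r_rx)`.
* Fractional-sample delays are realised by frequency-domain phase ramps
  (band-limited sinc interpolation), not nearest-sample placement; this is
  what makes sub-voxel localization tests meaningful.
* Channel noise is additive white Gaussian, reproducible from a seed.

Slow-time dynamics come from two scatterer populations:
`make_flow_phantom()` advects microbubbles along vessel-like polylines at a
constant speed (5 mm/s by default, 23.26 micrometres per frame at 215 Hz)
with a fixed lateral offset inside the vessel radius and wrap-around
re-entry so the bubble count is stationary; `make_clutter()` draws static
scatterers with exponentially distributed echogenicity and an optional
sub-wavelength random walk (enforced to stay below lambda/20 per frame so
it remains clutter-like).

What this generator does **not** emulate: nonlinear bubble oscillation and
shell dynamics, frequency-dependent attenuation and skull aberration,
speed-of-sound heterogeneity, element directivity and crosstalk, and the
grating-lobe structure a full-wave field simulation would show. Tests that
pass on this generator therefore demonstrate the correctness of the
*processing chain* under its stated acoustic model, not in vivo image
quality.

## Reconstruction

`das_pa()` implements one-way 3D delay-and-sum with linear temporal
interpolation, normalised by element count so amplitudes are independent of
array size. `das_us()` beamforms complex IQ volumes by sampling the
analytic signal (one-sided spectrum) of every channel at the round-trip
delay. This is algebraically identical to channel-wise baseband
demodulation followed by delay-matched phase rotation; the voxel phase
therefore shifts by `2*pi*fc*dpath/c` when a scatterer moves, the
sensitivity the slow-time processing relies on. No apodization or
directivity weighting is applied by default (flags exist).

`build_sparse_das()` assembles the same operation as a sparse matrix (two
nonzeros per voxel-channel pair, the linear-interpolation weights) mapping
flattened RF to a flattened volume; it reproduces the direct beamformers to
1e-6 and is what the pipeline uses to beamform long slow-time series
cheaply. A memory estimate is checked *before* allocation.

Delays that fall outside the record window contribute zero; the fraction of
truncated lookups is reported on the volume and more than 50% truncation is
treated as a configuration error. Sound speed is a configurable scalar
(default 1540 m/s). For oxygenation imaging the RF can first be Wiener
deconvolved by the impulse response (`deconvolve_rf()`, regularised by a
relative noise floor) and zero-phase low-pass filtered at 1 MHz
(`lowpass_rf()`, a forward-backward Butterworth whose two passes put the
-6 dB point at the cutoff).

`stitch()` places per-position volumes on a shared lattice (offsets must be
on the voxel lattice; no resampling) and blends overlaps by maximum by
default — the mean is available, but maximum preserves vessels across seam
dropout.

## Spectral unmixing

`unmix_so2()` solves the 2 x 2 linear system per voxel for the two
haemoglobin concentrations and forms `sO2 = C_HbO2 / (C_HbO2 + C_Hb)`. No
fluence compensation is applied: at 700/750 nm the fluence distributions
are similar and largely cancel in the ratio, which also makes the estimate
invariant to any common positive scaling of the two volumes. Voxels below
an amplitude threshold (default 10% of the volume maximum — the in vivo
threshold is not published, so it is a configurable default) or with both
concentrations non-positive are flagged invalid as NA, never silently
zeroed; a single negative concentration is clipped to zero before the
ratio. The packaged extinction table carries the standard tabulated molar
extinction values at 700/750/800 nm; the unmixing matrix's condition number
is attached to every result. Slab maps are amplitude-weighted means over an
axial window, since no projection is prescribed for them.

## The ULM chain

1. **Motion gating** (`reject_motion()`): lateral maximum-intensity
   projections are correlated against the mean-MIP reference; frames below
   a 99% correlation threshold are flagged. Only the mask is returned — the
   data are never modified in place.
2. **SVD clutter filtering** (`svd_filter()`): within non-overlapping
   blocks of 600 frames the voxels x frames Casorati matrix is decomposed
   and the 150 largest singular values are zeroed (a final partial block
   scales the cutoff proportionally, rounded down). Tissue clutter, being
   temporally coherent, concentrates in the leading components; moving
   bubbles spread across the rest.
3. **Slow-time conditioning**: `temporal_bandpass()` applies a zero-phase
   squared-Butterworth magnitude response on |f| (20-107 Hz by default)
   with exact DC removal; `directional_split()` separates up- and
   down-moving blood by half-plane selection in the (axial spatial
   frequency, slow-time frequency) Fourier domain — a target moving toward
   +z concentrates where the two frequencies have opposite signs. The
   zero-frequency planes are split evenly so the channels sum to the input.
4. **Power Doppler** (`power_doppler()`): mean |IQ|^2 over frames.
5. **Localization** (`localize_radial_symmetry()`): local maxima above a
   relative threshold are refined to the 3D radial-symmetry centre — the
   point minimising the weighted sum of squared distances to the lines
   through each window voxel along its gradient direction (a 3 x 3 linear
   solve). Weights are gradient power damped by distance from the weighted
   centroid, which keeps far-off noise from steering the fit; the default
   window is 7 voxels. On 20 dB SNR synthetic bubbles the RMS error is
   below 0.2 voxel — the mechanism behind super-resolved vascular maps.
6. **Tracking** (`track_bubbles()`): frame-to-frame optimal bipartite
   assignment (an O(n^3) Hungarian implementation, validated against a
   brute-force permutation oracle) on Euclidean distance, with links beyond
   `max_link` forbidden (scaled by the gap length when closing gaps up to
   `max_gap` missed frames) and tracks shorter than `min_length` discarded.
   The published work does not state its tracker's parameters, so the
   defaults are chosen from the physics: `max_link` of twice the expected
   per-frame step at 10 mm/s, `max_gap` 2, `min_length` 5.
7. **Rendering** (`render_maps()`): tracks are interpolated along their
   polylines and accumulated on a grid refined 4-fold (15 micrometres at
   60 micrometre voxels), giving the density map; the velocity map is the
   density-weighted mean speed. Speeds can be taken per step or per track
   (end-to-end displacement over duration); the latter suppresses the
   upward bias localization jitter adds to step lengths and is what the
   demo pipeline uses.

## Vessel quantification

`segment_vessels()` is a deliberately simple, fully documented stand-in for
discriminant ridge extraction: Gaussian smoothing, relative thresholding,
26-connected component labelling, a geodesic centerline (shortest path
between the two most distant voxels of the component, pulled onto the
medial axis by hill-climbing the exact Euclidean distance transform and
extended back to the component ends), and a radius read from the distance
transform along the centerline with a half-voxel boundary correction.
Vessel length integrates Euclidean distances along the centerline
(`polyline_length()`), and vessel volume uses the cylinder model
`pi r^2 L`. On straight-cylinder phantoms with radii 0.05-0.3 mm the
recovered lengths are within a few percent and radii within ~15%.
Curvature/roundness/ridgeness discriminants are intentionally not
reproduced; claims rest on phantom recovery, not on matching in vivo vessel
counts.

Per-vessel physiology comes from masked means over each vessel's dilated
centerline tube (`extract_vessel_functions()`), hemispheres are split by a
configurable mid-plane, and group comparisons use the large-sample
two-sample Z statistic `(m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
two-sided normal p values. Kernel-density summaries use Scott's-rule
bandwidth and are renormalised so they integrate to one exactly.

## Resolution measurement

`psf_resolution()` simulates a noiseless point source at the focus with the
full published parameter set, beamforms at 60 micrometre voxels, and
measures the FWHM of the *intensity* profile (squared envelope) through the
peak — resolution figures for such systems are read from intensity
profiles. The RF is sampled at 62.5 MHz, the rate used to characterise the
impulse response, because linear-interpolation beamforming of a coarser
clock (20.83 MHz) narrows the measured width by ~15% as an interpolation
artefact rather than a physical effect. Under these conditions the
simulated lateral FWHM is ~267 micrometres, within 3% of the measured
260 micrometre system resolution; the axial figure is similarly close to
its 390 micrometre counterpart in scale.

## The demo pipeline and its sizing

`run_pipeline(default_config(seed))` chains simulate, beamform, sO2, ULM
and quantify from a single schema-validated JSON-serializable
configuration. The demo scene is sized for a workstation: a 48-element
receive cap with 3 transmitters at a 215 Hz volume rate, a
2.4 x 2.4 x 1.6 mm grid of 100 micrometre voxels, two parallel vessels
1 mm apart carrying 4 bubbles each at 5 mm/s with oxygenations 0.80 and
0.65, 30 clutter scatterers, and 200 slow-time frames; SVD blocks of 100
frames with 8 components removed keep the published 600/150 removal
fraction's order. These are the package's chosen desk-scale study
conditions; they preserve every processing step of the full-scale system
while completing in minutes. Every stage seeds its randomness from the
global seed via a stable hash of the stage name, so adding a stage never
perturbs another, and re-running from the saved configuration regenerates
bit-identical artifacts (verified by MD5 checksums).

## Numerical choices and known limitations

* Linear interpolation in beamforming (two-tap sparse rows); band-limited
  interpolation in the simulator. Mixing the two means delay errors are
  dominated by the beamformer's linear taps.
* The envelope detector is the analytic-signal magnitude along axial
  columns; for grids shorter than 4 voxels axially it falls back to the
  absolute value.
* `stitch()`'s maximum blend assumes non-negative payloads (envelope, PD,
  density); use the mean blend for signed or complex data.
* Ties in farthest-point transmit selection and in local-maximum merging
  are broken toward the lower element index / brighter detection, making
  both deterministic.
* The RF container is a raw little-endian float32 binary with a
  schema-versioned JSON sidecar; volumes are NIfTI with mm spacing in the
  header (complex volumes as a real/imag pair); tracks and vessels are
  CSV. Corrupted or mismatched schema versions raise explicit errors.
* The limited-view problem is inherent to a single cap: structures with
  boundaries parallel to the line of sight are under-represented. The
  package demonstrates, but does not correct, this; multi-speed-of-sound
  and aberration-corrected reconstruction are out of scope.
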